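# minimal hand-built acquisition: one head, uniform PW counts, no scatter
.mock_planar <- function(pw_total, lsw = 0, usw = 0, iso = "I131",
                         n_decays = 1e6) {
  n <- 8
  mk <- function(total) array(total / n^2, dim = c(1, n, n))
  structure(list(
    mode = "planar",
    counts = list(PW = mk(pw_total), LSW = mk(lsw), USW = mk(usw)),
    primary_counts = mk(pw_total),
    expected = NULL, spectra = matrix(0, 10, 4),
    meta = list(isotope = iso, phantom = "A", windows = get_windows(iso),
                n_decays = n_decays)), class = "acquisition")
}

test_that("planar CF reproduces the defining arithmetic", {
  acq <- .mock_planar(30000)
  r <- cf_planar(acq, activity = 10, duration = 300, use_expected = FALSE)
  expect_equal(r$cf, 10)
  expect_equal(r$uncertainty, r$cf / sqrt(30000))

  # the printed magnitude of the reference experiment #1
  r2 <- cf_planar(.mock_planar(87480), activity = 5, duration = 300,
                  use_expected = FALSE)
  expect_equal(r2$cf, 58.32)

  # simulation denominator: counts per decay in cps/MBq
  r3 <- cf_planar(.mock_planar(30000, n_decays = 1e6), use_expected = FALSE)
  expect_equal(r3$cf, 30000 / 1e6 * 1e6)

  expect_error(cf_planar(.mock_planar(100), activity = -1, duration = 10,
                         use_expected = FALSE), "positive")
  # scatter windows so hot that the corrected total goes negative
  bad <- .mock_planar(10, lsw = 1e4, usw = 1e4)
  expect_error(cf_planar(bad, use_expected = FALSE), "not positive")
})

test_that("tomographic CF follows the counts/(A n_p t_p) convention", {
  rec <- structure(list(image = array(1.2e6 / 64, dim = c(4, 4, 4)),
                        voxel_size = 9.58, grid_shape = 4,
                        params = list()), class = "recon_image")
  r <- cf_tomographic(rec, total_activity = 100, n_projections = 60,
                      t_per_projection = 20)
  expect_equal(r$cf, 1.2e6 / (100 * 60 * 20))  # 10 cps/MBq

  r2 <- cf_tomographic(rec, n_projections = 60, n_decays = 1e6)
  expect_equal(r2$cf, 1.2e6 / (60 * 1e6) * 1e6)

  expect_error(cf_tomographic(rec, total_activity = 0, n_projections = 60,
                              t_per_projection = 20), "positive")
})

test_that("CF is invariant to simultaneous scaling of counts and activity", {
  for (k in c(0.5, 3, 10)) {
    a <- cf_planar(.mock_planar(40000), activity = 8, duration = 500,
                   use_expected = FALSE)$cf
    b <- cf_planar(.mock_planar(40000 * k), activity = 8 * k,
                   duration = 500, use_expected = FALSE)$cf
    expect_equal(a, b, tolerance = 1e-12)
  }
})

test_that("planar CF on simulated data uses TEW or primary counts as requested", {
  acq <- fx_planar("Re188")
  pwsc <- cf_planar(acq)
  pp <- cf_planar(acq, use_primary = TRUE)
  expect_equal(pwsc$method, "CF_PWSC")
  expect_equal(pp$method, "CF_PPsim")
  expect_gt(pwsc$cf, 0)
  # TEW-corrected and primary CF agree within 10% for the point source
  expect_equal(pwsc$cf / pp$cf, 1, tolerance = 0.1)
  # tomographic input is rejected
  expect_error(cf_planar(fx_spect_b("Re188")$acq), "planar")
})

test_that("the study driver emits the full CF table deterministically", {
  res <- run_calibration_study(isotopes = "Lu177", mc_scale = 2e-5,
                               count_scale = 2e-2, configurations = "B",
                               include_primary = FALSE,
                               n_projections = 10, seed = 77)
  expect_setequal(res$method, c("CF_PWSC", "CF_PPsim", "CF_Rsim^B"))
  expect_true(all(res$cf > 0))
  res2 <- run_calibration_study(isotopes = "Lu177", mc_scale = 2e-5,
                                count_scale = 2e-2, configurations = "B",
                                include_primary = FALSE,
                                n_projections = 10, seed = 77)
  expect_identical(res, res2)  # bit-for-bit reproducible
})
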