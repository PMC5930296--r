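test_that("normalized CF tables have unit reference rows and published ratios", {
  res <- data.frame(
    isotope = rep(c("Re188", "I131"), each = 2),
    configuration = c("A", "B", "A", "D"),
    method = c("CF_PWSC", "CF_Rsim^B", "CF_PWSC", "CF_Rsim^D"),
    cf = c(17.60, 20.47, 65.74, 66.54),
    uncertainty = 0, counts = 1e5)
  out <- compare_cf(res, reference_method = "CF_PWSC")
  expect_equal(out$cf_normalized[out$method == "CF_PWSC"], c(1, 1))
  expect_equal(out$cf_normalized[out$isotope == "Re188" &
                                 out$method == "CF_Rsim^B"],
               20.47 / 17.60, tolerance = 1e-12)
  expect_equal(round(out$cf_normalized[out$isotope == "I131" &
                                       out$method == "CF_Rsim^D"], 3), 1.012)

  # scale invariance of the normalized table
  res2 <- res; res2$cf <- res2$cf * 37
  out2 <- compare_cf(res2, "CF_PWSC")
  expect_equal(out2$cf_normalized, out$cf_normalized)

  expect_error(compare_cf(res[res$method != "CF_PWSC", ], "CF_PWSC"),
               "missing")
})

test_that("ROI scatter bias partitions additively and flags degenerate input", {
  fx <- fx_spect_b("Lu177")
  roi <- source_roi(fx$phantom, fx$acq$meta$camera)
  bg <- region_spec("background_roi", radius_px = roi$radius_px)
  whole <- region_spec("entire_image")
  b_src <- roi_scatter_bias(fx$acq, roi)
  b_bg <- roi_scatter_bias(fx$acq, bg)
  b_all <- roi_scatter_bias(fx$acq, whole)
  expect_equal(b_src$tew_estimate + b_bg$tew_estimate, b_all$tew_estimate,
               tolerance = 1e-9)
  expect_equal(b_src$true_scatter + b_bg$true_scatter, b_all$true_scatter,
               tolerance = 1e-9)

  # zero-scatter acquisition: ratio undefined, not an error
  fake <- fx$acq
  fake$expected$PW <- fake$expected$primary
  fake$expected$LSW[] <- 0; fake$expected$USW[] <- 0
  b0 <- roi_scatter_bias(fake, whole)
  expect_true(is.na(b0$ratio))
  expect_equal(b0$true_scatter, 0)

  noexp <- fx$acq; noexp$expected <- NULL
  expect_error(roi_scatter_bias(noexp, roi), "unavailable")
})

test_that("TEW bias sign pattern is robust to the ROI radius", {
  fx <- fx_spect_b("Lu177")
  for (scale in c(1.2, 1.5, 2.0)) {
    roi <- source_roi(fx$phantom, fx$acq$meta$camera, scale = scale)
    bg <- region_spec("background_roi", radius_px = roi$radius_px)
    expect_lt(roi_scatter_bias(fx$acq, roi)$ratio, 1)
    expect_gt(roi_scatter_bias(fx$acq, bg)$ratio, 1)
  }
})

test_that("spectra report tabulates all components and rejects empty input", {
  acq <- fx_planar("Re188")
  tab <- spectra_report(list(acq))
  expect_setequal(unique(tab$component),
                  c("primary", "phantom_scatter", "camera_scatter",
                    "septal_penetration"))
  expect_equal(sum(tab$counts), sum(acq$spectra))
  expect_error(spectra_report(list()), "empty")

  # Lu177 point source has a cleaner photopeak window than I131
  # (high-energy camera scatter): PW scatter-to-total ratio ordering
  scat_frac <- function(a) {
    w <- a$meta$windows
    e <- seq_len(nrow(a$spectra)) - 0.5
    pwb <- e >= w$pw$lo & e <= w$pw$hi
    1 - sum(a$spectra[pwb, "primary"]) / sum(a$spectra[pwb, ])
  }
  expect_lt(scat_frac(fx_planar("Lu177")), scat_frac(fx_planar("I131")))

  # plot writes a file
  f <- tempfile(fileext = ".png")
  plot_spectra(acq, file = f)
  expect_true(file.exists(f) && file.size(f) > 0)
})
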