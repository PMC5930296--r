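test_that("emission sampling follows intensities, geometry and isotropy", {
  ph <- make_configuration("B", "Re188")
  em <- sample_emissions("Re188", ph, n_decays = 1e5, seed = 3)

  # expected 155-keV photons: N * 0.156 within 3 sigma Poisson
  n155 <- sum(em$energy == 155)
  expect_lt(abs(n155 - 1e5 * 0.156), 3 * sqrt(1e5 * 0.156))

  # cold background: all emissions inside the 100-mL sphere
  r <- sqrt(em$x^2 + em$y^2 + em$z^2)
  rs <- (3 * 100 / (4 * pi))^(1 / 3)
  expect_true(all(r <= rs + 1e-9))

  # isotropy: mean direction vector ~ (0,0,0) within 3 sigma of 1/sqrt(3n)
  n <- nrow(em)
  for (comp in c("ux", "uy", "uz"))
    expect_lt(abs(mean(em[[comp]])), 3 / sqrt(3 * n) * sqrt(3))

  expect_error(sample_emissions("Re188", ph, n_decays = 0), "positive")
})

test_that("Compton kinematics and Klein-Nishina sampling are correct", {
  expect_equal(compton_energy(364, pi), 364 / (1 + 2 * 364 / 511))
  expect_equal(compton_energy(364, pi), 150.1, tolerance = 1e-3)
  expect_equal(compton_energy(100, 0), 100)

  # sampled scattering-angle distribution matches the analytic KN pdf
  cost <- spectcal:::mc_kahn_sample_cpp(364, 2e5, 42)
  f <- function(ct) kn_dsigma(364, acos(ct))
  norm <- integrate(f, -1, 1)$value
  m_true <- integrate(function(ct) ct * f(ct), -1, 1)$value / norm
  v_true <- integrate(function(ct) ct^2 * f(ct), -1, 1)$value / norm - m_true^2
  expect_lt(abs(mean(cost) - m_true), 4 * sqrt(v_true / length(cost)))
  # total KN cross section consistent with the angular integral
  expect_equal(2 * pi * norm, kn_sigma_total(364), tolerance = 1e-6)
})

test_that("narrow-beam transmission matches exp(-mu L)", {
  for (case in list(c(364, 10), c(155, 5))) {
    E <- case[1]; L <- case[2]
    p <- pencil_beam_transmission(E, L, n = 1e5, seed = 7)
    p0 <- exp(-mu_linear("water", E) * L)
    expect_lt(abs(p - p0), 3 * sqrt(p0 * (1 - p0) / 1e5))
  }
})

test_that("single-photon transport honors its contracts", {
  ph_air <- make_configuration("A", "I131")
  out <- transport_photon(ph_air, c(0, 0, 0), c(0, 1, 0), 364)
  expect_equal(out$n_scatters, 0)
  expect_equal(out$energy, 364)
  expect_false(out$absorbed)

  ph <- make_configuration("D", "Lu177")
  expect_error(transport_photon(ph, c(0, 0, 0), c(0, 2, 0), 208),
               "unit vector")
})

test_that("planar simulation is linear in decays and rejects bad input", {
  ph <- make_configuration("A", "I131")
  a1 <- simulate_planar(ph, n_decays = 2e5, seed = 9)
  a2 <- simulate_planar(ph, n_decays = 4e5, seed = 10)
  r <- sum(a2$expected$PW) / sum(a1$expected$PW)
  expect_equal(r, 2, tolerance = 0.05)

  expect_error(simulate_planar(ph, n_decays = 0), "positive")
  phd <- make_configuration("D", "Lu177")
  phd$compartments[[1]]$conc <- 0
  expect_error(simulate_planar(phd, n_decays = 100), "zero total activity")
})

test_that("detected spectra show the photopeak at the line energy with the configured resolution", {
  acq <- fx_planar("Lu177")
  sp <- rowSums(acq$spectra)
  e <- seq_along(sp) - 0.5
  win <- e > 208 - 30 & e < 208 + 30
  centroid <- sum(e[win] * sp[win]) / sum(sp[win])
  expect_lt(abs(centroid - 208), 0.5)

  # FWHM from half-max crossings vs the configured model
  pk <- max(sp[win])
  idx <- which(win)[sp[win] >= pk / 2]
  fwhm_meas <- e[max(idx)] - e[min(idx)] + 1
  fwhm_model <- 0.099 * sqrt(140 * 208)
  expect_equal(fwhm_meas, fwhm_model, tolerance = 0.05)
})

test_that("forced detection agrees with analog sampling (config A)", {
  ph <- make_configuration("A", "I131")
  fd <- simulate_planar(ph, n_decays = 2e5, seed = 21)
  an <- simulate_planar(ph, n_decays = 4e6, seed = 22, analog = TRUE)
  lam_fd <- sum(fd$expected$PW) / 2e5     # per decay, both heads
  n_an <- sum(an$counts$PW)
  lam_an <- n_an / 4e6
  # analog counting noise dominates
  expect_lt(abs(lam_an - lam_fd), 3.5 * sqrt(n_an) / 4e6)
  expect_true(is.null(an$expected))
})

test_that("replicated projections are Poisson around the expectation", {
  fx <- fx_spect_b("Re188")
  pw <- fx$acq$counts$PW            # [90, n, n]
  lam <- fx$acq$expected$PW
  sel <- which(lam > 10, arr.ind = TRUE)
  expect_gt(nrow(sel), 20)
  mn <- vr <- numeric(nrow(sel))
  for (i in seq_len(nrow(sel))) {
    v <- pw[, sel[i, 1], sel[i, 2]]
    mn[i] <- mean(v); vr[i] <- var(v)
  }
  expect_equal(mean(vr / mn), 1, tolerance = 0.1)    # Poisson: var = mean
  expect_equal(mean(mn / lam[sel]), 1, tolerance = 0.05)
  expect_equal(fx$acq$meta$n_projections, 90)
})

test_that("event weights are conserved and primary fraction drops from A to B", {
  acqA <- fx_planar("I131")
  expect_lte(acqA$meta$sum_weights, acqA$meta$n_emitted)

  fB <- fx_spect_b("I131")
  primA <- sum(acqA$expected$primary) / sum(acqA$expected$PW)
  primB <- sum(fB$acq$expected$primary) / sum(fB$acq$expected$PW)
  expect_gt(primA, primB)  # phantom scatter dilutes the primary fraction
})

test_that("tomographic replication requires an axisymmetric phantom", {
  ph <- make_configuration("B", "Lu177")
  ph$compartments[[2]]$center <- c(3, 0, 0)
  expect_error(simulate_spect(ph, n_decays = 1e4), "symmetric")
})
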