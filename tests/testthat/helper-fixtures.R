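# Shared fixtures: medium-sized simulation runs are expensive, so they are
# computed lazily once per test session and cached here. All fixtures are
# generated in code with fixed seeds; nothing is read from disk.

.fix <- new.env(parent = emptyenv())

fixture_seed <- 20260911L

# Planar point-source acquisition (config A), MC histories at 1e-2 of the
# reference budget.
fx_planar <- function(iso) {
  key <- paste0("planar_", iso)
  if (is.null(.fix[[key]])) {
    ph <- make_configuration("A", iso)
    nd <- study_decays(iso, 1e-2)
    .fix[[key]] <- simulate_planar(ph, n_decays = nd$A, seed = fixture_seed)
  }
  .fix[[key]]
}

# Tomographic hot-sphere-in-cold-background acquisition (config B):
# MC histories at 1e-2 of the reference budget, Poisson counts at the full
# reference level (the replicate-mode convention).
fx_spect_b <- function(iso) {
  key <- paste0("spectB_", iso)
  if (is.null(.fix[[key]])) {
    ph <- make_configuration("B", iso)
    nd <- study_decays(iso, 1)
    ndmc <- study_decays(iso, 1e-2)
    .fix[[key]] <- list(
      phantom = ph,
      acq = simulate_spect(ph, n_decays = nd$B, mc_decays = ndmc$B,
                           seed = fixture_seed))
  }
  .fix[[key]]
}

fx_recon_b <- function(iso, primary = FALSE) {
  key <- paste0("reconB_", iso, if (primary) "_pp" else "")
  if (is.null(.fix[[key]])) {
    fx <- fx_spect_b(iso)
    .fix[[key]] <- reconstruct(fx$acq, fx$phantom, use_primary = primary)
  }
  .fix[[key]]
}

# small reconstruction geometry helpers
fx_small_geometry <- function(n = 32, n_angles = 8, seed = 1) {
  set.seed(seed)
  mu <- array(0, dim = c(n, n, n))
  ctr <- (1:n) - (n + 1) / 2
  r2 <- outer(ctr^2, ctr^2, `+`)
  cyl <- r2 <= (n / 3)^2
  for (k in seq_len(n)) mu[, , k] <- 0.15 * cyl
  list(n = n, mu = mu,
       map = structure(list(mu = mu, voxel_size = 9.58, energy = 208,
                            grid_shape = n), class = "attenuation_map"),
       angles = seq(0, 2 * pi, length.out = n_angles + 1)[1:n_angles])
}
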