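# Synthetic acquisition: R-level wrappers around the forced-detection
# Monte Carlo kernel. Produces multi-window planar and (replicated)
# tomographic projections with per-component detected-energy spectra and
# full provenance metadata.

#' Gamma-camera model parameters
#'
#' Defaults describe a dual-head camera with a 0.95-cm NaI(Tl) crystal,
#' 9.9% FWHM energy resolution at 140 keV (scaling as 1/sqrt(E)), and
#' representative high-energy (HE) or medium-energy (ME) parallel-hole
#' collimators. The septal-penetration solid-angle factor
#' (`kappa_penetration`) and the effective backscatter compartment behind
#' the crystal (`backscatter_slab_cm` water-equivalent, return factor
#' `kappa_backscatter`) are the acknowledged tuning surface of the
#' simplified camera model.
#'
#' @param collimator `"HE"` (I-131, Re-188) or `"ME"` (Lu-177).
#' @param npix detector pixels per axis.
#' @param pixel_mm pixel size in mm (matches the reconstruction grid).
#' @param dist_cm source-to-collimator distance in cm.
#' @param ... overrides for any other parameter.
#' @return named list of camera parameters.
#' @export
camera_model <- function(collimator = c("HE", "ME"), npix = 64,
                         pixel_mm = 9.58, dist_cm = 25, ...) {
  collimator <- match.arg(collimator)
  coll <- switch(collimator,
                 HE = list(hole_diameter_cm = 0.40, hole_length_cm = 5.97,
                           septa_cm = 0.20),
                 ME = list(hole_diameter_cm = 0.294, hole_length_cm = 4.064,
                           septa_cm = 0.114))
  base <- c(list(collimator = collimator, npix = as.integer(npix),
                 pixel_cm = pixel_mm / 10, dist_cm = dist_cm,
                 crystal_cm = 0.95, fwhm_frac = 0.099, fwhm_eref_kev = 140,
                 shape_K = 0.26, kappa_penetration = 10,
                 backscatter_slab_cm = 5, kappa_backscatter = 1.0), coll)
  modifyList(base, list(...))
}

#' Default collimator for an isotope (as used in the reference experiments)
#' @param isotope isotope identifier.
#' @return `"HE"` or `"ME"`.
#' @export
default_collimator <- function(isotope) {
  switch(isotope, I131 = "HE", Re188 = "HE", Lu177 = "ME",
         stop("unsupported isotope '", isotope, "'"))
}

# phantom_model -> C++ geometry description (analytic solids at the origin).
# When a camera is given, a water-occupancy map on the camera's pixel grid
# is attached: the forced-detection exit attenuation then uses the same
# discretized water columns as the reconstruction system model.
.phantom_cpp <- function(phantom, activities = NULL, camera = NULL) {
  comps <- phantom$compartments
  act <- compartment_activities(phantom, activities = activities)
  water <- list(shape = 0L, radius = 0, halflen = 0)
  cyl <- NULL; sph <- NULL
  for (cp in comps) {
    if (cp$shape == "cylinder") cyl <- cp else sph <- cp
  }
  if (!is.null(cyl) && cyl$material == "water")
    water <- list(shape = 2L, radius = cyl$radius, halflen = cyl$length / 2)
  else if (!is.null(sph) && sph$material == "water")
    water <- list(shape = 1L, radius = sph$radius, halflen = 0)
  rows <- lapply(seq_along(comps), function(i) {
    cp <- comps[[i]]
    if (cp$shape == "sphere")
      c(1, cp$radius, 0, 0, act$weight[i])
    else {
      inner <- if (!is.null(sph)) sph$radius else 0
      c(if (inner > 0) 3 else 2, cp$radius, cp$length / 2, inner,
        act$weight[i])
    }
  })
  occ <- NULL; occ_n <- 0L; occ_vs <- 0
  if (!is.null(camera) && water$shape != 0L) {
    amap <- make_attenuation_map(phantom, grid_shape = camera$npix,
                                 voxel_size = camera$pixel_cm * 10)
    occ <- amap$mu / mu_linear("water", amap$energy)
    occ_n <- camera$npix
    occ_vs <- camera$pixel_cm
  }
  list(water_shape = water$shape, water_radius = water$radius,
       water_halflen = water$halflen,
       sources = do.call(rbind, rows),
       occupancy = occ, occ_n = occ_n, occ_voxel_cm = occ_vs)
}

.windows_cpp <- function(windows) {
  rbind(c(windows$pw$lo, windows$pw$hi),
        c(windows$lsw$lo, windows$lsw$hi),
        c(windows$usw$lo, windows$usw$hi))
}

.lines_cpp <- function(iso) as.matrix(iso$lines)

# deterministic substream seeds below 2^31 from a master seed and a label
.derive_seed <- function(master, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  (as.numeric(master) * 48271 + h * 16807) %% 2147483629 + 1
}

.run_projection <- function(phantom, iso, windows, camera, n_decays, seed,
                            analog = FALSE, activities = NULL) {
  mc_projection_cpp(.phantom_cpp(phantom, activities, camera), camera,
                    .windows_cpp(windows), .lines_cpp(iso),
                    n_decays, seed,
                    .xs_dense("water"), .xs_dense("nai"), .xs_dense("pb"),
                    analog = analog)
}

.new_acquisition <- function(mode, counts, primary, expected, spectra,
                             meta) {
  out <- list(mode = mode, counts = counts, primary_counts = primary,
              expected = expected, spectra = spectra, meta = meta)
  class(out) <- "acquisition"
  out
}

#' Simulate a planar acquisition
#'
#' Runs the forced-detection Monte Carlo for a static dual-head acquisition:
#' one projection per head, per energy window, plus component-tagged
#' detected-energy spectra and the primary-photon truth map in the
#' photopeak window. Counts are Poisson realizations of the
#' forced-detection expectation maps (unless `analog = TRUE`, in which case
#' they are directly sampled events).
#'
#' @param phantom a `phantom_model` (typically configuration A).
#' @param isotope isotope identifier; defaults to `phantom$isotope`.
#' @param n_decays number of decays to simulate.
#' @param windows a `window_triplet`; default windows for the isotope.
#' @param camera a [camera_model()]; default chosen by isotope.
#' @param seed master seed (integer).
#' @param analog use analog (no variance reduction) detection.
#' @param activities optional explicit per-compartment activities.
#' @return an `acquisition` with `counts` (list PW/LSW/USW of
#'   `[head, row, col]` arrays), `primary_counts`, `expected` (the
#'   forced-detection expectation maps), `spectra` (energy bin x component)
#'   and metadata.
#' @export
simulate_planar <- function(phantom, isotope = phantom$isotope,
                            n_decays, windows = NULL, camera = NULL,
                            seed = 1, analog = FALSE, activities = NULL) {
  if (n_decays <= 0) stop("n_decays must be positive")
  iso <- get_isotope(isotope)
  if (is.null(windows)) windows <- get_windows(iso$name)
  if (is.null(camera)) camera <- camera_model(default_collimator(iso$name))
  res <- .run_projection(phantom, iso, windows, camera, n_decays,
                         .derive_seed(seed, "planar-mc"), analog = analog,
                         activities = activities)
  np <- camera$npix
  # windows array [x, z, window(PW,LSW,USW), head] -> list of [head, z, x]
  lam <- lapply(1:3, function(w) {
    arr <- array(0, dim = c(2, np, np))
    for (h in 1:2) arr[h, , ] <- t(res$windows[, , w, h])
    arr
  })
  names(lam) <- c("PW", "LSW", "USW")
  lam_p <- array(0, dim = c(2, np, np))
  for (h in 1:2) lam_p[h, , ] <- t(res$primary[, , h])
  if (analog) {
    counts <- lam
    primary <- lam_p
    expected <- NULL
  } else {
    set.seed(.derive_seed(seed, "planar-noise"))
    counts <- lapply(lam, function(a)
      array(as.double(rpois(length(a), a)), dim = dim(a)))
    primary <- array(as.double(rpois(length(lam_p), lam_p)), dim = dim(lam_p))
    expected <- c(lam, list(primary = lam_p))
  }
  spectra <- res$spectra
  colnames(spectra) <- c("primary", "phantom_scatter", "camera_scatter",
                         "septal_penetration")
  .new_acquisition("planar", counts, primary, expected, spectra,
                   meta = list(isotope = iso$name, phantom = phantom$label,
                               windows = windows, camera = camera,
                               n_decays = n_decays, seed = seed,
                               analog = analog,
                               n_emitted = res$n_emitted,
                               sum_weights = res$sum_weights))
}

#' Simulate a tomographic (SPECT) acquisition by projection replication
#'
#' For cylindrically symmetric phantoms a single high-statistics projection
#' is simulated with forced detection; its head-averaged expectation is then
#' replicated over `n_projections` uniformly spaced angles with independent
#' Poisson noise. Each projection corresponds to `n_decays` simulated
#' decays (the calibration denominator is therefore
#' `n_projections * n_decays`).
#'
#' @inheritParams simulate_planar
#' @param n_projections number of projection angles over 360 degrees.
#' @param mc_decays number of Monte Carlo histories actually run (default
#'   `n_decays`). When smaller, the forced-detection expectation maps are
#'   scaled up to the `n_decays` level before the Poisson replication:
#'   projection noise then matches the stated decay budget while the Monte
#'   Carlo cost stays at desk scale (the residual MC error on the
#'   expectation is common to all projections).
#' @return an `acquisition` with `counts` (list PW/LSW/USW of
#'   `[n_projections, row, col]` arrays), `primary_counts`, `expected`
#'   per-projection expectation maps, `spectra`, angle metadata.
#' @export
simulate_spect <- function(phantom, isotope = phantom$isotope, n_decays,
                           windows = NULL, camera = NULL,
                           n_projections = 90, seed = 1,
                           activities = NULL, mc_decays = n_decays) {
  if (n_decays <= 0 || mc_decays <= 0) stop("n_decays must be positive")
  if (!.axisymmetric(phantom))
    stop("projection replication requires a phantom that is cylindrically ",
         "symmetric about the rotation axis")
  iso <- get_isotope(isotope)
  if (is.null(windows)) windows <- get_windows(iso$name)
  if (is.null(camera)) camera <- camera_model(default_collimator(iso$name))
  res <- .run_projection(phantom, iso, windows, camera, mc_decays,
                         .derive_seed(seed, "spect-mc"),
                         activities = activities)
  np <- camera$npix
  scale <- n_decays / mc_decays
  # head-averaged expectation per window, [row(z), col(x)]
  avg <- function(w)
    scale * (t(res$windows[, , w, 1]) + t(res$windows[, , w, 2])) / 2
  lam <- list(PW = avg(1), LSW = avg(2), USW = avg(3))
  lam_p <- scale * (t(res$primary[, , 1]) + t(res$primary[, , 2])) / 2
  set.seed(.derive_seed(seed, "spect-noise"))
  repl <- function(l) {
    arr <- array(0, dim = c(n_projections, np, np))
    for (p in seq_len(n_projections))
      arr[p, , ] <- array(as.double(rpois(length(l), l)), dim = dim(l))
    arr
  }
  counts <- lapply(lam, repl)
  primary <- repl(lam_p)
  spectra <- res$spectra
  colnames(spectra) <- c("primary", "phantom_scatter", "camera_scatter",
                         "septal_penetration")
  angles <- seq(0, 2 * pi, length.out = n_projections + 1)[1:n_projections]
  .new_acquisition("tomographic", counts, primary,
                   c(lam, list(primary = lam_p)), spectra,
                   meta = list(isotope = iso$name, phantom = phantom$label,
                               windows = windows, camera = camera,
                               n_decays = n_decays, mc_decays = mc_decays,
                               seed = seed,
                               n_projections = n_projections,
                               angles = angles,
                               n_emitted = res$n_emitted,
                               sum_weights = res$sum_weights))
}

.axisymmetric <- function(phantom) {
  all(vapply(phantom$compartments, function(cp)
    all(abs(cp$center[1:2]) < 1e-9), logical(1)))
}

#' @export
print.acquisition <- function(x, ...) {
  cat(sprintf("<acquisition> %s, %s config %s, %.3g decays\n", x$mode,
              x$meta$isotope, x$meta$phantom, x$meta$n_decays))
  cat(sprintf("  PW counts %.0f (primary %.0f)\n",
              sum(x$counts$PW), sum(x$primary_counts)))
  invisible(x)
}

#' Sample emission positions and directions (diagnostics)
#'
#' Exposes the Monte Carlo emission sampler: positions uniform within each
#' compartment (compartment chosen by activity weight), each gamma line
#' emitted independently with its intensity, isotropic directions.
#'
#' @param isotope `isotope_spec` or identifier.
#' @param phantom a `phantom_model`.
#' @param n_decays decays to sample.
#' @param seed integer seed.
#' @return data.frame with columns `x, y, z, ux, uy, uz, energy`.
#' @export
sample_emissions <- function(isotope, phantom, n_decays, seed = 1) {
  if (n_decays <= 0) stop("n_decays must be positive")
  iso <- if (inherits(isotope, "isotope_spec")) isotope else get_isotope(isotope)
  res <- mc_sample_emissions_cpp(.phantom_cpp(phantom), .lines_cpp(iso),
                                 n_decays, .derive_seed(seed, "emit"))
  as.data.frame(res)
}

#' Transport a single photon through the phantom (diagnostics)
#'
#' Tracks one photon through the phantom's water region with sampled free
#' paths, photoelectric absorption and Klein-Nishina Compton scattering,
#' returning the state at phantom exit (or absorption).
#'
#' @param phantom a `phantom_model`.
#' @param position,direction numeric length-3; `direction` must be unit.
#' @param energy keV.
#' @param seed integer seed.
#' @return list with `position`, `direction`, `energy`, `n_scatters`,
#'   `absorbed`.
#' @export
transport_photon <- function(phantom, position, direction, energy, seed = 1) {
  mc_transport_photon_cpp(.phantom_cpp(phantom), as.numeric(position),
                          as.numeric(direction), energy,
                          .derive_seed(seed, "transport"),
                          .xs_dense("water"))
}

#' Pencil-beam transmission through water (oracle hook)
#'
#' Fires `n` photons through `length_cm` of water using the transport
#' sampler and returns the unscattered-transmission frequency, for
#' comparison against `exp(-mu * L)`.
#'
#' @param energy keV.
#' @param length_cm water path length.
#' @param n number of photons.
#' @param seed integer seed.
#' @return transmitted fraction.
#' @export
pencil_beam_transmission <- function(energy, length_cm, n = 1e5, seed = 1) {
  mc_pencil_beam_cpp(energy, length_cm, n, .derive_seed(seed, "pencil"),
                     .xs_dense("water"))
}
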