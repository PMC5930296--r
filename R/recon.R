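# TEW scatter estimation and OSEM reconstruction with attenuation
# correction and an additive scatter term in the denominator.

#' Triple-energy-window (TEW) scatter estimate
#'
#' Trapezoidal estimator: per pixel,
#' `S = (C_L / W_L + C_U / W_U) * W_P / 2`, with window widths recomputed
#' from the window bounds. The estimate is never subtracted from the data
#' inside the reconstruction; it enters the OSEM denominator additively.
#'
#' @param pw,lsw,usw congruent count arrays (photopeak, lower and upper
#'   scatter windows).
#' @param windows a `window_triplet` supplying the window widths.
#' @return array of estimated scatter counts in the photopeak window, same
#'   shape as `pw`, all values non-negative.
#' @export
#' @examples
#' w <- get_windows("I131")
#' tew_estimate(pw = matrix(100, 2, 2), lsw = matrix(22, 2, 2),
#'              usw = matrix(22, 2, 2), windows = w)
tew_estimate <- function(pw, lsw, usw, windows) {
  if (!all(dim(pw) == dim(lsw)) || !all(dim(pw) == dim(usw)))
    stop("PW/LSW/USW arrays must have identical shapes")
  if (min(pw, lsw, usw) < 0) stop("negative input counts")
  wl <- window_width(windows$lsw)
  wu <- window_width(windows$usw)
  wp <- window_width(windows$pw)
  (lsw / wl + usw / wu) * wp / 2
}

#' Attenuated parallel-beam forward projection
#'
#' Rotation-based projector: for each angle the volume is rotated so the
#' detector sits along +y; each voxel's contribution is weighted by
#' `exp(-integral of mu)` from the voxel to the detector (half-voxel
#' self-attenuation). With `mu = 0` the projector conserves counts.
#'
#' @param image 3-D array (counts per voxel), cubic grid.
#' @param mu_map an `attenuation_map` (or a bare 3-D array in 1/cm).
#' @param angles projection angles in radians.
#' @param voxel_mm voxel size in mm (taken from `mu_map` when available).
#' @return array `[n, n, n_angles]` of projections (x by z by angle).
#' @export
forward_project <- function(image, mu_map, angles, voxel_mm = NULL) {
  mu <- if (inherits(mu_map, "attenuation_map")) mu_map$mu else mu_map
  if (is.null(voxel_mm))
    voxel_mm <- if (inherits(mu_map, "attenuation_map")) mu_map$voxel_size
                else stop("voxel_mm required")
  if (!all(dim(image) == dim(mu))) stop("image and mu map are not congruent")
  forward_project_cpp(image, mu, dim(image)[1], angles, voxel_mm / 10)
}

#' Adjoint of [forward_project()]
#'
#' @param projections array `[n, n, n_angles]`.
#' @inheritParams forward_project
#' @return 3-D image-like array.
#' @export
back_project <- function(projections, mu_map, angles, voxel_mm = NULL) {
  mu <- if (inherits(mu_map, "attenuation_map")) mu_map$mu else mu_map
  if (is.null(voxel_mm))
    voxel_mm <- if (inherits(mu_map, "attenuation_map")) mu_map$voxel_size
                else stop("voxel_mm required")
  n <- dim(mu)[1]
  if (!all(dim(projections)[1:2] == c(n, n)) ||
      dim(projections)[3] != length(angles))
    stop("projection stack does not match mu map / angle list")
  back_project_cpp(projections, mu, n, angles, voxel_mm / 10)
}

#' Reconstruction parameter defaults per isotope
#'
#' Lu-177 and Re-188: 6 iterations x 10 subsets; I-131: 35 iterations x
#' 6 subsets; the quebec protocol uses 12 subsets (96 projections).
#'
#' @param isotope isotope identifier.
#' @param dialect window dialect.
#' @return list with `iterations`, `subsets`.
#' @export
recon_defaults <- function(isotope, dialect = "default") {
  if (dialect == "quebec") return(list(iterations = 6, subsets = 12))
  switch(isotope,
         I131 = list(iterations = 35, subsets = 6),
         Lu177 = ,
         Re188 = list(iterations = 6, subsets = 10),
         stop("unsupported isotope '", isotope, "'"))
}

#' OSEM reconstruction with attenuation correction and additive scatter
#'
#' Ordered-subsets EM update
#' `x <- x * Pt_s[y / (P_s x + s)] / Pt_s[1]` over interleaved angle
#' subsets; the scatter estimate enters the denominator only, so negative
#' counts can never occur. Non-negativity of the image is preserved by the
#' multiplicative update.
#'
#' @param projections `[n_angles, n, n]` counts (as stored in an
#'   `acquisition`) or `[n, n, n_angles]` projector-ordered stack.
#' @param scatter congruent scatter estimate (e.g. from [tew_estimate()]),
#'   or `NULL` for no scatter term (primary-only reconstructions).
#' @param mu_map an `attenuation_map` congruent with the recon grid.
#' @param angles projection angles (radians), length `n_angles`.
#' @param iterations,subsets OSEM parameters; `subsets` must divide the
#'   number of angles.
#' @param eps denominator guard.
#' @param track_loglik record the Poisson log-likelihood after each full
#'   iteration.
#' @return a `recon_image`: list with `image` (3-D array, counts),
#'   `voxel_size` (mm), `params`, and optionally `loglik`.
#' @export
osem <- function(projections, scatter, mu_map, angles, iterations = 6,
                 subsets = 10, eps = 1e-12, track_loglik = FALSE) {
  n <- dim(mu_map$mu)[1]
  proj <- .proj_stack(projections, n, length(angles))
  sc <- if (is.null(scatter)) array(0, dim = dim(proj))
        else .proj_stack(scatter, n, length(angles))
  if (!all(dim(sc) == dim(proj)))
    stop("scatter estimate not congruent with projections")
  if (length(angles) %% subsets != 0)
    stop("subset count must divide the number of projection angles")
  res <- osem_cpp(proj, sc, mu_map$mu, n, angles, iterations, subsets,
                  mu_map$voxel_size / 10, eps, track_loglik)
  out <- list(image = res$image, voxel_size = mu_map$voxel_size,
              grid_shape = n,
              params = list(iterations = iterations, subsets = subsets,
                            n_angles = length(angles), eps = eps,
                            attenuation = TRUE,
                            scatter = !is.null(scatter)),
              loglik = if (track_loglik) res$loglik else NULL)
  class(out) <- "recon_image"
  out
}

# accept [n_angles, n, n] acquisition-ordered or [n, n, n_angles]
# projector-ordered stacks
.proj_stack <- function(x, n, n_angles) {
  d <- dim(x)
  if (length(d) != 3) stop("projections must be a 3-D array")
  if (d[1] == n_angles && d[2] == n && d[3] == n) {
    out <- array(0, dim = c(n, n, n_angles))
    for (a in seq_len(n_angles)) out[, , a] <- t(x[a, , ])  # [x, z]
    out
  } else if (d[1] == n && d[2] == n && d[3] == n_angles) {
    x
  } else stop("projection stack does not match grid/angles")
}

#' @export
print.recon_image <- function(x, ...) {
  cat(sprintf("<recon_image> %d^3 @ %.2f mm, %d it x %d subsets, total %.4g counts\n",
              x$grid_shape, x$voxel_size, x$params$iterations,
              x$params$subsets, sum(x$image)))
  invisible(x)
}

#' Reconstruct a tomographic acquisition
#'
#' Convenience wrapper: builds the TEW scatter estimate (or none for
#' primary-only data), the attenuation map at the photopeak energy, and
#' runs OSEM with the isotope's default parameters.
#'
#' The returned image is rescaled to whole-scan count units: [osem()]
#' reconstructs an image whose forward projection matches a single
#' projection, so its total is multiplied by the number of projections.
#' Total image counts are then directly comparable with the total counts
#' acquired over the scan, the convention used for tomographic calibration
#' factors.
#'
#' @param acq a tomographic `acquisition`.
#' @param phantom the `phantom_model` that was imaged (for the mu map).
#' @param use_primary reconstruct the primary-photon projections with
#'   attenuation correction only (no scatter term).
#' @param iterations,subsets override [recon_defaults()].
#' @param grid_shape,voxel_mm reconstruction grid; default matches the
#'   acquisition pixel grid.
#' @return a `recon_image` (whole-scan count units).
#' @export
reconstruct <- function(acq, phantom, use_primary = FALSE,
                        iterations = NULL, subsets = NULL,
                        grid_shape = NULL, voxel_mm = NULL) {
  if (acq$mode != "tomographic")
    stop("reconstruction requires a tomographic acquisition")
  iso <- acq$meta$isotope
  defaults <- recon_defaults(iso, acq$meta$windows$dialect)
  if (is.null(iterations)) iterations <- defaults$iterations
  if (is.null(subsets)) subsets <- defaults$subsets
  if (is.null(grid_shape)) grid_shape <- acq$meta$camera$npix
  if (is.null(voxel_mm)) voxel_mm <- acq$meta$camera$pixel_cm * 10
  mu_map <- make_attenuation_map(phantom, grid_shape = grid_shape,
                                 voxel_size = voxel_mm)
  angles <- acq$meta$angles
  rec <- if (use_primary) {
    osem(acq$primary_counts, NULL, mu_map, angles, iterations, subsets)
  } else {
    sc <- tew_estimate(acq$counts$PW, acq$counts$LSW, acq$counts$USW,
                       acq$meta$windows)
    osem(acq$counts$PW, sc, mu_map, angles, iterations, subsets)
  }
  rec$image <- rec$image * length(angles)  # whole-scan count units
  rec$params$whole_scan_units <- TRUE
  rec
}
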