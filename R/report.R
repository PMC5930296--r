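# Diagnostic analyses: ROI-resolved TEW scatter bias (the mechanism behind
# the cold-background CF overestimation), normalized CF comparison tables,
# and component-layered energy spectra.

#' Circular region-of-interest specification on the projection plane
#'
#' The source ROI is a circle around the projected hot-object center; the
#' background ROI is everything outside it; together they partition the
#' image.
#'
#' @param kind `"source_roi"`, `"background_roi"` or `"entire_image"`.
#' @param center circle center in pixels `(row, col)`; defaults to the
#'   image center.
#' @param radius_px circle radius in pixels.
#' @return a `region_spec` list.
#' @export
region_spec <- function(kind = c("source_roi", "background_roi",
                                 "entire_image"),
                        center = NULL, radius_px = NULL) {
  kind <- match.arg(kind)
  structure(list(kind = kind, center = center, radius_px = radius_px),
            class = "region_spec")
}

.region_mask <- function(region, dims) {
  if (region$kind == "entire_image") return(matrix(TRUE, dims[1], dims[2]))
  ctr <- if (is.null(region$center)) (dims + 1) / 2 else region$center
  r2 <- outer((seq_len(dims[1]) - ctr[1])^2, (seq_len(dims[2]) - ctr[2])^2,
              `+`)
  inside <- r2 <= region$radius_px^2
  if (region$kind == "source_roi") inside else !inside
}

#' Default source ROI for a hot-sphere phantom
#'
#' A circle of 1.5 times the projected sphere radius, centered on the
#' projected sphere center.
#'
#' @param phantom a `phantom_model` containing a sphere.
#' @param camera the [camera_model()] of the acquisition.
#' @param scale ROI radius as a multiple of the projected sphere radius.
#' @return a `region_spec` of kind `"source_roi"`.
#' @export
source_roi <- function(phantom, camera, scale = 1.5) {
  sph <- Filter(function(cp) cp$shape == "sphere", phantom$compartments)
  if (length(sph) == 0) stop("phantom has no sphere compartment")
  r_px <- sph[[1]]$radius / camera$pixel_cm
  region_spec("source_roi", radius_px = scale * r_px)
}

#' ROI-resolved TEW scatter bias
#'
#' Compares, over a region of the projection plane, the true scatter counts
#' recorded in the photopeak window (every non-primary component, known
#' from the simulation tags) with the TEW estimate. The characteristic
#' pattern for a hot source in a cold background is underestimation
#' (ratio < 1) over the source ROI and overestimation (ratio > 1) over the
#' background.
#'
#' @param acq an `acquisition` with forced-detection expectation maps
#'   (simulation; experimental-style analog acquisitions carry no component
#'   tags and are rejected).
#' @param region a `region_spec`.
#' @param windows `window_triplet`; defaults to the acquisition's.
#' @return list with `true_scatter`, `tew_estimate`, `ratio`
#'   (TEW / truth, `NA` when the truth is zero), `region`.
#' @export
roi_scatter_bias <- function(acq, region, windows = acq$meta$windows) {
  if (is.null(acq$expected))
    stop("component-tagged expectation maps unavailable ",
         "(analog/experimental acquisition)")
  lam_pw <- acq$expected$PW
  lam_p <- acq$expected$primary
  # collapse heads/projections: expectation maps are [row, col] for
  # tomographic and [head, row, col] for planar
  coll <- function(a) if (length(dim(a)) == 3) apply(a, c(2, 3), sum) else a
  pw <- coll(lam_pw); pp <- coll(lam_p)
  lsw <- coll(acq$expected$LSW); usw <- coll(acq$expected$USW)
  mask <- .region_mask(region, dim(pw))
  truth <- sum((pw - pp)[mask])
  tew <- sum(tew_estimate(pw, lsw, usw, windows)[mask])
  list(true_scatter = truth, tew_estimate = tew,
       ratio = if (truth > 0) tew / truth else NA_real_, region = region)
}

#' Normalize calibration factors to a per-isotope reference method
#'
#' Divides every CF by its isotope's reference CF, so reference rows equal
#' one exactly; the result is invariant to global count rescaling.
#'
#' @param results data.frame from [run_calibration_study()] (or a list of
#'   `calibration_result`s).
#' @param reference_method method label used as reference, e.g.
#'   `"CF_PWSC"` or `"CF_PPsim"`.
#' @return the input data.frame with a `cf_normalized` column.
#' @export
compare_cf <- function(results, reference_method = "CF_PWSC") {
  if (!is.data.frame(results))
    results <- do.call(rbind, lapply(results, function(r) data.frame(
      isotope = r$isotope, configuration = r$configuration,
      method = r$method, cf = r$cf, uncertainty = r$uncertainty,
      counts = r$counts)))
  results$cf_normalized <- NA_real_
  for (iso in unique(results$isotope)) {
    sel <- results$isotope == iso
    ref <- results$cf[sel & results$method == reference_method]
    if (length(ref) != 1)
      stop("reference method '", reference_method,
           "' missing (or not unique) for isotope ", iso)
    results$cf_normalized[sel] <- results$cf[sel] / ref
  }
  results
}

#' Component-layered energy spectra report
#'
#' Assembles the detected-energy spectra of a set of acquisitions into a
#' long table (energy bin, component, counts, isotope, configuration), the
#' machine-readable companion of the usual layered spectrum plot.
#'
#' @param acqs list of `acquisition`s.
#' @return data.frame with `isotope`, `configuration`, `energy_kev`,
#'   `component`, `counts`.
#' @export
spectra_report <- function(acqs) {
  if (length(acqs) == 0) stop("empty acquisition list")
  do.call(rbind, lapply(acqs, function(a) {
    sp <- a$spectra
    nb <- nrow(sp)
    data.frame(isotope = a$meta$isotope, configuration = a$meta$phantom,
               energy_kev = rep(seq_len(nb) - 0.5, ncol(sp)),
               component = rep(colnames(sp), each = nb),
               counts = as.vector(sp))
  }))
}

#' Plot layered spectra for one acquisition
#'
#' @param acq an `acquisition`.
#' @param file optional path for a PNG; otherwise draws on the active device.
#' @param max_kev upper energy bound of the plot.
#' @return invisibly, the spectra matrix.
#' @export
plot_spectra <- function(acq, file = NULL, max_kev = 800) {
  sp <- acq$spectra
  e <- seq_len(nrow(sp)) - 0.5
  keep <- e <= max_kev
  if (!is.null(file)) grDevices::png(file, width = 900, height = 600)
  tot <- rowSums(sp)
  graphics::plot(e[keep], tot[keep], type = "l", lwd = 2,
                 xlab = "energy [keV]", ylab = "counts (weighted)",
                 main = sprintf("%s config %s", acq$meta$isotope,
                                acq$meta$phantom))
  cols <- c(primary = "blue", phantom_scatter = "red",
            camera_scatter = "darkgreen", septal_penetration = "orange")
  for (cc in colnames(sp))
    graphics::lines(e[keep], sp[keep, cc], col = cols[[cc]])
  w <- acq$meta$windows
  graphics::abline(v = c(w$lsw$lo, w$pw$lo, w$pw$hi, w$usw$hi), lty = 3)
  graphics::legend("topright", legend = c("total", colnames(sp)),
                   col = c("black", cols[colnames(sp)]), lwd = 1)
  if (!is.null(file)) grDevices::dev.off()
  invisible(sp)
}
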