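# Analytic phantom configurations A-D and voxelized attenuation maps.
#
# Coordinate convention: right-handed, phantom axis along z (the tomographic
# rotation axis), detector heads along +/- y. Lengths in cm internally;
# voxel sizes are stated in mm at the interfaces. Grids are centered on the
# phantom center; with 0-based indices, voxel centers sit at
# (index + 0.5) * voxel_size - extent/2.

.sphere_radius_for_volume <- function(volume_ml) (3 * volume_ml / (4 * pi))^(1 / 3)

.compartment_volume <- function(cp) {
  if (cp$shape == "sphere") 4 / 3 * pi * cp$radius^3
  else pi * cp$radius^2 * cp$length
}

#' Build one of the four calibration phantom configurations
#'
#' Configuration A is a 1-mL point-like source in air; B is a 100-mL hot
#' sphere centered in a cold 20-cm-diameter, 19.1-cm-long water cylinder
#' (about 6 L); C is the same sphere in a warm background with a 6:1
#' sphere-to-background activity-concentration ratio; D is the cylinder
#' uniformly filled with activity.
#'
#' @param label `"A"`, `"B"`, `"C"` or `"D"`.
#' @param isotope isotope identifier (stored in metadata; also sets the
#'   default attenuation-map energy downstream).
#' @param params optional overrides: `sphere_volume_ml`, `cylinder_diameter_cm`,
#'   `cylinder_length_cm`, `concentration_ratio` (config C),
#'   `total_activity_MBq`, `source_to_collimator_cm`.
#' @return a `phantom_model`: list with `label`, `isotope`, `compartments`
#'   (ordered; later compartments override earlier ones in overlaps),
#'   `source_to_collimator` (cm) and `total_activity` (MBq, may be `NA`).
#' @export
#' @examples
#' make_configuration("B", "Lu177")
make_configuration <- function(label, isotope = "Lu177", params = list()) {
  label <- match.arg(label, c("A", "B", "C", "D"))
  iso <- get_isotope(isotope)  # validates isotope
  p <- modifyList(list(sphere_volume_ml = if (label == "A") 1 else 100,
                       cylinder_diameter_cm = 20,
                       cylinder_length_cm = 19.1,
                       concentration_ratio = 6,
                       total_activity_MBq = NA_real_,
                       source_to_collimator_cm = 25), params)
  if (p$concentration_ratio <= 0 || p$sphere_volume_ml <= 0)
    stop("geometry/activity parameters must be positive")

  rs <- .sphere_radius_for_volume(p$sphere_volume_ml)
  rc <- p$cylinder_diameter_cm / 2
  sphere <- function(conc, material = "water")
    list(shape = "sphere", center = c(0, 0, 0), radius = rs,
         material = material, conc = conc)
  cylinder <- function(conc)
    list(shape = "cylinder", center = c(0, 0, 0), radius = rc,
         length = p$cylinder_length_cm, axis = "z",
         material = "water", conc = conc)

  # the configuration-A point source is treated as non-attenuating (air):
  # the reference planar calibration minimizes attenuation in the source
  comps <- switch(label,
    A = list(sphere(1, material = "air")),
    B = list(cylinder(0), sphere(1)),
    C = list(cylinder(1), sphere(p$concentration_ratio)),
    D = list(cylinder(1)))

  if (label %in% c("B", "C") && rs >= rc)
    stop("sphere does not fit inside the cylinder")
  if (any(vapply(comps, function(cp) cp$conc < 0, logical(1))))
    stop("negative activity concentration")

  out <- list(label = label, isotope = iso$name, compartments = comps,
              source_to_collimator = p$source_to_collimator_cm,
              total_activity = p$total_activity_MBq)
  class(out) <- "phantom_model"
  if (label == "C") {
    act <- compartment_activities(out)
    conc <- act$activity / act$volume_ml
    ratio <- max(conc) / min(conc)
    if (abs(ratio - 6) > 0.1 && is.null(params$concentration_ratio))
      stop("config C concentration ratio deviates from 6:1")
  }
  out
}

#' @export
print.phantom_model <- function(x, ...) {
  cat(sprintf("<phantom_model> config %s (%s), %d compartment(s)\n",
              x$label, x$isotope, length(x$compartments)))
  act <- compartment_activities(x)
  for (i in seq_len(nrow(act)))
    cat(sprintf("  %-8s %-5s %7.1f mL  weight %.4f\n", act$shape[i],
                act$material[i], act$volume_ml[i], act$weight[i]))
  invisible(x)
}

#' Per-compartment volumes, activities and decay-sampling weights
#'
#' Volumes account for overlap overrides (a sphere placed inside the
#' cylinder removes its volume from the cylinder compartment). Decay weights
#' are proportional to compartment activity (concentration times volume) and
#' sum to one.
#'
#' @param phantom a `phantom_model`.
#' @param activities optional explicit per-compartment activities (same
#'   order as `phantom$compartments`), overriding concentration-derived ones;
#'   used e.g. to mirror a published decay budget exactly.
#' @return data.frame with `shape`, `material`, `volume_ml`, `activity`
#'   (relative units unless `phantom$total_activity` is set), `weight`.
#' @export
compartment_activities <- function(phantom, activities = NULL) {
  comps <- phantom$compartments
  vols <- vapply(comps, .compartment_volume, numeric(1))
  # later compartments carve their volume out of earlier enclosing ones
  for (i in seq_along(comps)) {
    for (j in seq_len(i - 1)) {
      if (comps[[i]]$shape == "sphere" && comps[[j]]$shape == "cylinder")
        vols[j] <- vols[j] - vols[i]
    }
  }
  act <- if (is.null(activities))
    vapply(seq_along(comps), function(i) comps[[i]]$conc * vols[i], numeric(1))
  else as.numeric(activities)
  if (sum(act) <= 0) stop("phantom has zero total activity")
  if (!is.na(phantom$total_activity))
    act <- act / sum(act) * phantom$total_activity
  data.frame(shape = vapply(comps, `[[`, "", "shape"),
             material = vapply(comps, `[[`, "", "material"),
             volume_ml = vols, activity = act, weight = act / sum(act))
}

#' Voxelized narrow-beam attenuation map
#'
#' Fills a cubic grid with the linear attenuation coefficient of water at
#' the stated energy inside water compartments and zero elsewhere (air is
#' treated as vacuum). Boundary voxels get a fractional coefficient from
#' 2x-per-axis sub-sampled occupancy, which keeps voxelized volumes within
#' about 2% of the analytic ones.
#'
#' @param phantom a `phantom_model`.
#' @param energy map energy in keV; defaults to the isotope's photopeak line.
#' @param grid_shape voxels per axis (cubic grid), default 64.
#' @param voxel_size voxel edge in mm, default 9.58.
#' @return an `attenuation_map`: list with `mu` (3-D array, 1/cm),
#'   `voxel_size` (mm), `energy` (keV), `grid_shape`.
#' @export
make_attenuation_map <- function(phantom, energy = NULL, grid_shape = 64,
                                 voxel_size = 9.58) {
  if (is.null(energy)) energy <- photopeak_energy(phantom$isotope)
  n <- as.integer(grid_shape)
  vs <- voxel_size / 10  # cm
  extent <- n * vs
  water <- Filter(function(cp) cp$material == "water", phantom$compartments)
  for (cp in water) {
    r_needed <- if (cp$shape == "sphere") cp$radius
                else max(cp$radius, cp$length / 2)
    if (r_needed > extent / 2) stop("grid too small to contain phantom")
  }
  mu_w <- mu_linear("water", energy)
  # sub-sampled voxel-center coordinates (2 per axis)
  sub <- c(-0.25, 0.25) * vs
  centers <- (seq_len(n) - 0.5) * vs - extent / 2
  occ <- array(0, dim = c(n, n, n))
  for (cp in phantom$compartments) {
    frac <- array(0, dim = c(n, n, n))
    for (dz in sub) for (dy in sub) for (dx in sub) {
      x <- centers + dx; y <- centers + dy; z <- centers + dz
      if (cp$shape == "sphere") {
        r2 <- outer(outer((x - cp$center[1])^2, (y - cp$center[2])^2, `+`),
                    (z - cp$center[3])^2, `+`)
        frac <- frac + (r2 <= cp$radius^2)
      } else {
        rxy <- outer((x - cp$center[1])^2, (y - cp$center[2])^2, `+`)
        inz <- abs(z - cp$center[3]) <= cp$length / 2
        frac <- frac + outer(rxy <= cp$radius^2, inz, `&`)
      }
    }
    frac <- frac / 8
    val <- if (cp$material == "water") mu_w else 0
    # later compartments override earlier ones where they occupy the voxel
    occ <- occ * (1 - frac) + val * frac
  }
  out <- list(mu = occ, voxel_size = voxel_size, energy = energy,
              grid_shape = n)
  class(out) <- "attenuation_map"
  out
}

#' @export
print.attenuation_map <- function(x, ...) {
  cat(sprintf(
    "<attenuation_map> %d^3 voxels @ %.2f mm, %g keV, water-equivalent volume %.2f L\n",
    x$grid_shape, x$voxel_size, x$energy, attenuation_map_volume(x)))
  invisible(x)
}

#' Water-equivalent volume of an attenuation map
#' @param map an `attenuation_map`.
#' @return occupancy-weighted water volume in liters.
#' @export
attenuation_map_volume <- function(map) {
  mu_w <- mu_linear("water", map$energy)
  sum(map$mu) / mu_w * (map$voxel_size / 10)^3 / 1000
}
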