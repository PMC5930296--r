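# Radionuclide emission data and acquisition energy-window settings.
# Both are shipped as plain-text tables under inst/extdata and are the
# single source of truth: TEW window widths, photopeak energies and
# emission intensities are always re-derived from them.

.iso_env <- new.env(parent = emptyenv())

.iso_table <- function() {
  if (is.null(.iso_env$lines)) {
    f <- system.file("extdata", "gamma_lines.tsv", package = "spectcal",
                     mustWork = TRUE)
    .iso_env$lines <- read.delim(f, comment.char = "#")
  }
  .iso_env$lines
}

.win_table <- function() {
  if (is.null(.iso_env$windows)) {
    f <- system.file("extdata", "energy_windows.tsv", package = "spectcal",
                     mustWork = TRUE)
    .iso_env$windows <- read.delim(f, comment.char = "#")
  }
  .iso_env$windows
}

#' Supported radionuclides
#' @return character vector of isotope identifiers.
#' @export
supported_isotopes <- function() unique(.iso_table()$isotope)

#' Emission data for a therapy radionuclide
#'
#' Returns the principal gamma lines (energy in keV, emission probability
#' per decay) and the half-life of one of the supported therapy isotopes.
#' Only lines with intensity above 1% are modeled.
#'
#' @param name isotope identifier: `"I131"`, `"Lu177"` or `"Re188"`.
#' @return an object of class `isotope_spec`: list with `name`,
#'   `half_life` (seconds) and `lines` (data.frame with `energy`, `intensity`).
#' @export
#' @examples
#' get_isotope("Lu177")
get_isotope <- function(name) {
  tab <- .iso_table()
  rows <- tab[tab$isotope == name, , drop = FALSE]
  if (nrow(rows) == 0)
    stop("unsupported isotope '", name, "'; supported: ",
         paste(supported_isotopes(), collapse = ", "))
  out <- list(name = name,
              half_life = rows$half_life_s[1],
              lines = data.frame(energy = rows$energy_kev,
                                 intensity = rows$intensity))
  stopifnot(all(out$lines$energy > 0),
            all(out$lines$intensity > 0.01 & out$lines$intensity <= 1))
  class(out) <- "isotope_spec"
  out
}

#' @export
print.isotope_spec <- function(x, ...) {
  cat(sprintf("<isotope_spec> %s  half-life %.4g h\n",
              x$name, x$half_life / 3600))
  for (i in seq_len(nrow(x$lines)))
    cat(sprintf("  %4d keV  %5.1f%%\n",
                x$lines$energy[i], 100 * x$lines$intensity[i]))
  invisible(x)
}

#' Photopeak energy of an isotope
#'
#' The principal imaging line: the gamma line with the highest
#' intensity-weighted presence in the photopeak window (364 keV for I-131,
#' 208 keV for Lu-177, 155 keV for Re-188).
#'
#' @param isotope identifier or `isotope_spec`.
#' @return energy in keV.
#' @export
photopeak_energy <- function(isotope) {
  iso <- if (inherits(isotope, "isotope_spec")) isotope else get_isotope(isotope)
  w <- get_windows(iso$name)
  inpw <- iso$lines$energy >= w$pw$lo & iso$lines$energy <= w$pw$hi
  if (!any(inpw)) stop("no emission line inside the photopeak window")
  iso$lines$energy[inpw][which.max(iso$lines$intensity[inpw])]
}

#' Acquisition energy windows for an isotope
#'
#' Returns the photopeak window (PW) and the lower/upper scatter windows
#' (LSW/USW) used for TEW scatter correction. The `"quebec"` dialect (valid
#' for Lu-177 only) uses 21-keV scatter windows abutting the photopeak.
#'
#' @param isotope isotope identifier.
#' @param dialect `"default"` or `"quebec"`.
#' @return an object of class `window_triplet`: list with `pw`, `lsw`, `usw`
#'   (each `list(lo, hi, label)`), `dialect` and `isotope`. Window widths are
#'   derived from the bounds via [window_width()].
#' @export
#' @examples
#' get_windows("I131")
#' get_windows("Lu177", dialect = "quebec")
get_windows <- function(isotope, dialect = "default") {
  dialect <- match.arg(dialect, c("default", "quebec"))
  if (dialect == "quebec" && isotope != "Lu177")
    stop("the quebec window dialect is defined for Lu177 only")
  tab <- .win_table()
  rows <- tab[tab$isotope == isotope & tab$dialect == dialect, , drop = FALSE]
  if (nrow(rows) == 0)
    stop("no window settings for isotope '", isotope, "'")
  mk <- function(lbl) {
    r <- rows[rows$window == lbl, ]
    stopifnot(nrow(r) == 1, r$lo_kev < r$hi_kev)
    list(lo = r$lo_kev, hi = r$hi_kev, label = lbl)
  }
  out <- list(pw = mk("PW"), lsw = mk("LSW"), usw = mk("USW"),
              dialect = dialect, isotope = isotope)
  class(out) <- "window_triplet"
  out
}

#' Width of an energy window
#' @param w a window `list(lo, hi, ...)` as stored in a `window_triplet`.
#' @return width in keV.
#' @export
window_width <- function(w) w$hi - w$lo

#' @export
print.window_triplet <- function(x, ...) {
  cat(sprintf("<window_triplet> %s (%s)\n", x$isotope, x$dialect))
  for (w in list(x$lsw, x$pw, x$usw))
    cat(sprintf("  %-3s %3d-%3d keV (width %d)\n",
                w$label, w$lo, w$hi, window_width(w)))
  invisible(x)
}
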