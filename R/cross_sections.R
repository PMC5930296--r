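#' @useDynLib spectcal, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx rpois pnorm setNames
#' @importFrom utils read.delim modifyList
NULL

# Packaged cross-section tables, loaded once per session.
.xs_env <- new.env(parent = emptyenv())

.xs_load <- function(material) {
  key <- paste0("tab_", material)
  if (!is.null(.xs_env[[key]])) return(.xs_env[[key]])
  file <- system.file("extdata",
                      paste0("attenuation_", material, ".tsv"),
                      package = "spectcal", mustWork = TRUE)
  hdr <- readLines(file, n = 2L)
  density <- as.numeric(sub(".*density_g_cm3: *", "", hdr[2]))
  tab <- read.delim(file, comment.char = "#", check.names = FALSE)
  out <- list(energy = tab$energy_kev,
              pe = tab$photoelectric,
              incoherent = tab$incoherent,
              total = tab$total,
              density = density)
  .xs_env[[key]] <- out
  out
}

#' Linear attenuation coefficients from the packaged tables
#'
#' Looks up mass attenuation coefficients (photoelectric and incoherent;
#' coherent scattering is not modeled) for water, NaI(Tl) or lead, log-log
#' interpolated in energy, and converts them to linear coefficients using the
#' tabulated density. These tables are the single source of photon
#' cross-section data for both the Monte Carlo transport and the
#' attenuation maps used in reconstruction.
#'
#' @param material one of `"water"`, `"nai"`, `"pb"`.
#' @param energy photon energy in keV (vectorized); must lie within 30-1000.
#' @param component `"total"`, `"pe"` (photoelectric) or `"incoherent"`.
#' @return linear attenuation coefficient(s) in 1/cm.
#' @export
#' @examples
#' mu_linear("water", 364)   # ~0.110 1/cm
mu_linear <- function(material, energy, component = "total") {
  material <- match.arg(material, c("water", "nai", "pb"))
  component <- match.arg(component, c("total", "pe", "incoherent"))
  tab <- .xs_load(material)
  if (any(energy < min(tab$energy) | energy > max(tab$energy)))
    stop("energy outside the packaged cross-section range [",
         min(tab$energy), ", ", max(tab$energy), "] keV")
  y <- tab[[if (component == "pe") "pe" else component]]
  exp(approx(log(tab$energy), log(y), xout = log(energy))$y) * tab$density
}

# Dense 1-keV grids handed to the C++ transport kernel.
.xs_dense <- function(material, emin = 30, emax = 1000) {
  e <- seq(emin, emax, by = 1)
  list(energy = e,
       pe = mu_linear(material, e, "pe"),
       incoherent = mu_linear(material, e, "incoherent"),
       total = mu_linear(material, e, "total"))
}

#' Compton-scattered photon energy
#'
#' Closed-form Compton kinematics: a photon of energy `E` scattered through
#' angle `theta` emerges with `E / (1 + (E/511)(1 - cos(theta)))`.
#'
#' @param energy incident photon energy, keV.
#' @param theta scattering angle, radians.
#' @return scattered photon energy in keV.
#' @export
#' @examples
#' compton_energy(364, pi)  # 150.1 keV backscatter
compton_energy <- function(energy, theta) {
  energy / (1 + (energy / 511) * (1 - cos(theta)))
}

#' Klein-Nishina differential cross section
#'
#' Unnormalized differential cross section per solid angle for Compton
#' scattering of an unpolarized photon off a free electron, in units of
#' the classical electron radius squared.
#'
#' @param energy incident photon energy, keV.
#' @param theta scattering angle, radians.
#' @return dsigma/dOmega in units of r_e^2.
#' @export
kn_dsigma <- function(energy, theta) {
  r <- compton_energy(energy, theta) / energy
  0.5 * r^2 * (r + 1 / r - sin(theta)^2)
}

#' Klein-Nishina total cross section
#'
#' @param energy photon energy, keV.
#' @return total Compton cross section per electron, in units of r_e^2.
#' @export
kn_sigma_total <- function(energy) {
  eps <- energy / 511
  t1 <- (1 + eps) / eps^2 * (2 * (1 + eps) / (1 + 2 * eps) - log(1 + 2 * eps) / eps)
  t2 <- log(1 + 2 * eps) / (2 * eps)
  t3 <- (1 + 3 * eps) / (1 + 2 * eps)^2
  2 * pi * (t1 + t2 - t3)
}
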