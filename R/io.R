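# Configuration files, acquisition persistence (binary arrays + JSON
# sidecar), and a minimal Interfile 3.3 projection export.

.config_defaults <- function() list(
  isotope = "Lu177", config = "B", dialect = "default",
  mc_scale = 1e-3, n_projections = 90L,
  grid_shape = 64L, voxel_mm = 9.58,
  iterations = NULL, subsets = NULL,
  seed = 1L, output_dir = ".",
  camera = list())

#' Load and validate a study configuration
#'
#' Configurations are JSON objects (or flat `key: value` text files);
#' unknown keys are rejected, defaults are applied (90 projections, the
#' isotope's reconstruction parameters, default windows), and cross-field
#' constraints are checked (quebec dialect only with Lu-177, subsets must
#' divide the projection count).
#'
#' @param path file path, or a named list already in memory.
#' @return a validated `study_config` list.
#' @export
load_config <- function(path) {
  raw <- if (is.list(path)) {
    path
  } else {
    if (!file.exists(path)) stop("config file not found: ", path)
    txt <- readLines(path, warn = FALSE)
    if (grepl("^\\s*\\{", paste(txt, collapse = ""))) {
      jsonlite::fromJSON(paste(txt, collapse = "\n"), simplifyVector = TRUE)
    } else {  # key: value lines
      txt <- txt[nzchar(trimws(txt)) & !grepl("^\\s*#", txt)]
      kv <- strsplit(txt, ":", fixed = TRUE)
      vals <- lapply(kv, function(x) {
        v <- trimws(paste(x[-1], collapse = ":"))
        suppressWarnings(if (!is.na(as.numeric(v))) as.numeric(v) else v)
      })
      setNames(vals, trimws(vapply(kv, `[[`, "", 1)))
    }
  }
  defaults <- .config_defaults()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- modifyList(defaults, raw)
  if (!cfg$isotope %in% supported_isotopes())
    stop("config: unsupported isotope '", cfg$isotope, "'")
  if (!cfg$config %in% c("A", "B", "C", "D"))
    stop("config: configuration must be one of A, B, C, D")
  if (cfg$dialect == "quebec" && cfg$isotope != "Lu177")
    stop("config: quebec dialect is valid for Lu177 only")
  rd <- recon_defaults(cfg$isotope, cfg$dialect)
  if (is.null(cfg$iterations)) cfg$iterations <- rd$iterations
  if (is.null(cfg$subsets)) cfg$subsets <- rd$subsets
  if (cfg$n_projections %% cfg$subsets != 0)
    stop("config: subsets (", cfg$subsets, ") must divide n_projections (",
         cfg$n_projections, ")")
  if (cfg$mc_scale <= 0 || cfg$grid_shape < 8)
    stop("config: mc_scale must be positive and grid_shape >= 8")
  class(cfg) <- "study_config"
  cfg
}

#' Save an acquisition to disk
#'
#' Writes every count/expectation array as little-endian float64 binary
#' next to a JSON sidecar holding shapes, window bounds, seeds, decays and
#' angles, for a lossless round trip via [load_acquisition()].
#'
#' @param acq an `acquisition`.
#' @param path directory (created if missing).
#' @return invisibly, `path`.
#' @export
save_acquisition <- function(acq, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  arrays <- list()
  put <- function(name, a) {
    if (is.null(a)) return()
    f <- file.path(path, paste0(name, ".f64"))
    con <- file(f, "wb")
    writeBin(as.vector(a), con, size = 8, endian = "little")
    close(con)
    arrays[[name]] <<- dim(a)
  }
  for (w in names(acq$counts)) put(paste0("counts_", w), acq$counts[[w]])
  put("primary_counts", acq$primary_counts)
  if (!is.null(acq$expected))
    for (w in names(acq$expected)) put(paste0("expected_", w),
                                       acq$expected[[w]])
  put("spectra", acq$spectra)
  meta <- acq$meta
  meta$windows <- unclass(meta$windows)
  sidecar <- list(mode = acq$mode, arrays = arrays, meta = meta,
                  spectra_components = colnames(acq$spectra),
                  byte_order = "little", dtype = "float64")
  jsonlite::write_json(sidecar, file.path(path, "acquisition.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load an acquisition saved by [save_acquisition()]
#' @param path directory containing `acquisition.json`.
#' @return an `acquisition`.
#' @export
load_acquisition <- function(path) {
  sidecar_file <- file.path(path, "acquisition.json")
  if (!file.exists(sidecar_file)) stop("missing sidecar: ", sidecar_file)
  sc <- jsonlite::fromJSON(sidecar_file, simplifyVector = TRUE)
  get_arr <- function(name) {
    dims <- sc$arrays[[name]]
    if (is.null(dims)) return(NULL)
    f <- file.path(path, paste0(name, ".f64"))
    if (!file.exists(f)) stop("missing array file: ", f)
    con <- file(f, "rb")
    v <- readBin(con, "double", n = prod(dims), size = 8, endian = "little")
    close(con)
    array(v, dim = dims)
  }
  counts <- list(PW = get_arr("counts_PW"), LSW = get_arr("counts_LSW"),
                 USW = get_arr("counts_USW"))
  expected <- NULL
  if (!is.null(sc$arrays$expected_PW))
    expected <- list(PW = get_arr("expected_PW"),
                     LSW = get_arr("expected_LSW"),
                     USW = get_arr("expected_USW"),
                     primary = get_arr("expected_primary"))
  spectra <- get_arr("spectra")
  colnames(spectra) <- sc$spectra_components
  meta <- sc$meta
  meta$windows <- structure(lapply(meta$windows[c("pw", "lsw", "usw")],
                                   as.list),
                            class = "window_triplet")
  meta$windows$dialect <- sc$meta$windows$dialect
  meta$windows$isotope <- sc$meta$windows$isotope
  .new_acquisition(sc$mode, counts, get_arr("primary_counts"), expected,
                   spectra, meta)
}

#' Export projections as an Interfile 3.3 header + raw image pair
#'
#' Writes the photopeak-window projections (float64, little endian) with a
#' minimal Interfile header, for interoperability with nuclear-medicine
#' tooling.
#'
#' @param acq an `acquisition`.
#' @param stem output path stem (writes `<stem>.hv` and `<stem>.v`).
#' @param window which window to export.
#' @return invisibly, the header path.
#' @export
export_interfile <- function(acq, stem, window = "PW") {
  arr <- acq$counts[[window]]
  d <- dim(arr)
  datafile <- paste0(stem, ".v")
  con <- file(datafile, "wb")
  writeBin(as.vector(arr), con, size = 8, endian = "little")
  close(con)
  hdr <- c(
    "!INTERFILE :=",
    "!imaging modality := nucmed",
    "!version of keys := 3.3",
    sprintf("!name of data file := %s", basename(datafile)),
    "!type of data := Tomographic",
    sprintf("!total number of images := %d", d[1]),
    "!number format := float",
    "!number of bytes per pixel := 8",
    "imagedata byte order := LITTLEENDIAN",
    sprintf("!matrix size [1] := %d", d[3]),
    sprintf("!matrix size [2] := %d", d[2]),
    sprintf("!number of projections := %d", d[1]),
    sprintf("scaling factor (mm/pixel) [1] := %g",
            acq$meta$camera$pixel_cm * 10),
    sprintf("scaling factor (mm/pixel) [2] := %g",
            acq$meta$camera$pixel_cm * 10),
    sprintf("energy window lower level [1] := %g", acq$meta$windows$pw$lo),
    sprintf("energy window upper level [1] := %g", acq$meta$windows$pw$hi),
    "!END OF INTERFILE :=")
  hv <- paste0(stem, ".hv")
  writeLines(hdr, hv)
  invisible(hv)
}

#' Read back the raw array of an Interfile export
#' @param stem path stem used in [export_interfile()].
#' @return numeric array with the dimensions recorded in the header.
#' @export
read_interfile <- function(stem) {
  hdr <- readLines(paste0(stem, ".hv"))
  grab <- function(key) {
    ln <- grep(key, hdr, fixed = TRUE, value = TRUE)[1]
    as.numeric(trimws(sub(".*:=", "", ln)))
  }
  d <- c(grab("!number of projections"), grab("!matrix size [2]"),
         grab("!matrix size [1]"))
  con <- file(paste0(stem, ".v"), "rb")
  v <- readBin(con, "double", n = prod(d), size = 8, endian = "little")
  close(con)
  array(v, dim = d)
}
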