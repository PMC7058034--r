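#' Write a plate image to 16-bit grayscale TIFF or PNG
#'
#' Intensities are stored exactly: the integer raster in \[0, 65535\] is
#' written at 16 bits per sample and read back bit-identically.  No
#' rescaling is ever applied.
#'
#' @param plate A `plate_image`.
#' @param path Output path for the fluorescence channel; the format is
#'   chosen by the extension (`.tif`/`.tiff` or `.png`).
#' @param bf_path Optional output path for the bright-field channel.
#' @param sidecar_path Optional path for the ground-truth JSON sidecar.
#' @return Invisibly, the paths written.
#' @export
write_plate_image <- function(plate, path, bf_path = NULL,
                              sidecar_path = NULL) {
  stopifnot(inherits(plate, "plate_image"))
  write_one <- function(m, p) {
    norm <- m / 65535
    ext <- tolower(tools::file_ext(p))
    if (ext %in% c("tif", "tiff")) {
      tiff::writeTIFF(norm, p, bits.per.sample = 16L)
    } else if (ext == "png") {
      write_png16(m, p)  # png::writePNG caps at 8 bits per sample
    } else {
      stop("unsupported image extension: ", ext)
    }
  }
  write_one(plate$fluor, path)
  written <- path
  if (!is.null(bf_path)) {
    if (is.null(plate$bf)) stop("plate has no bright-field channel")
    write_one(plate$bf, bf_path)
    written <- c(written, bf_path)
  }
  if (!is.null(sidecar_path)) {
    write_sidecar(plate$truth, sidecar_path)
    written <- c(written, sidecar_path)
  }
  invisible(written)
}

#' Read a plate image from 16-bit TIFF or PNG
#'
#' @param path Fluorescence image path.
#' @param bf_path Optional bright-field image path.
#' @param pixel_size Pixel size (mm/px).
#' @param concentration Concentration (mM) associated with the plate.
#' @param plate_id Plate identifier.
#' @param sidecar_path Optional ground-truth sidecar to attach.
#' @return A `plate_image`.
#' @export
read_plate_image <- function(path, bf_path = NULL, pixel_size,
                             concentration = NA_real_,
                             plate_id = basename(path),
                             sidecar_path = NULL) {
  read_one <- function(p) {
    ext <- tolower(tools::file_ext(p))
    norm <- if (ext %in% c("tif", "tiff")) tiff::readTIFF(p)
            else if (ext == "png") png::readPNG(p)
            else stop("unsupported image extension: ", ext)
    m <- round(norm * 65535)
    storage.mode(m) <- "integer"
    m
  }
  truth <- if (!is.null(sidecar_path)) read_sidecar(sidecar_path) else NULL
  out <- list(fluor = read_one(path),
              bf = if (!is.null(bf_path)) read_one(bf_path) else NULL,
              pixel_size = pixel_size, concentration = concentration,
              plate_id = plate_id, truth = truth)
  class(out) <- "plate_image"
  out
}

#' @rdname write_plate_image
#' @param truth A plate ground-truth list (`plate_image$truth`).
#' @export
write_sidecar <- function(truth, sidecar_path) {
  jsonlite::write_json(truth, sidecar_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(sidecar_path)
}

#' @rdname read_plate_image
#' @export
read_sidecar <- function(sidecar_path) {
  truth <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  if (!is.null(truth$colonies)) {
    truth$colonies <- as.data.frame(truth$colonies)
  } else {
    truth$colonies <- data.frame()
  }
  truth
}

#' Read and write colony record tables
#'
#' Colony records travel as CSV with the fixed header `plate_id,
#' colony_id, concentration_mM, center_row_px, center_col_px, radius_px,
#' diameter_mm, mean_fluor, sector_score, sectored, qc_flags` (plus
#' `phenotype` once classified).
#'
#' @param records Colony record data frame.
#' @param path CSV path.
#' @return `read_colony_table` returns the data frame; writers return the
#'   path invisibly.
#' @export
write_colony_table <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_colony_table
#' @export
read_colony_table <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plate_id", "colony_id", "concentration_mM", "center_row_px",
            "center_col_px", "radius_px", "diameter_mm", "mean_fluor",
            "sector_score", "sectored", "qc_flags")
  missing <- setdiff(need, names(rec))
  if (length(missing)) stop("colony table lacks column(s): ",
                            paste(missing, collapse = ", "))
  rec$sectored <- as.logical(rec$sectored)
  rec$qc_flags[is.na(rec$qc_flags)] <- ""
  rec
}

#' Read and write dose--response truth tables and event samples
#'
#' Truth tables are CSV with columns `concentration_mM, p_gfp_pos,
#' p_sector`; event samples are single-column CSV (`intensity`).
#'
#' @param truth,path,events Table/paths as appropriate.
#' @return Readers return the object; writers the path, invisibly.
#' @export
write_truth_table <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_table
#' @export
read_truth_table <- function(path) {
  tt <- utils::read.csv(path)
  stopifnot(all(c("concentration_mM", "p_gfp_pos", "p_sector") %in%
                  names(tt)))
  tt
}

#' @rdname write_truth_table
#' @export
write_events <- function(events, path) {
  v <- if (inherits(events, "event_sample")) events$events else events
  utils::write.csv(data.frame(intensity = v), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_table
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path)
  structure(list(events = as.numeric(df[[1]]), gate = NA_real_,
                 positive_fraction = NA_real_), class = "event_sample")
}

#' Load a simulation configuration from a YAML file
#'
#' Keys mirror the arguments of [sim_config()]; absent keys keep their
#' defaults.  Nested models (`intensity_model`, `diameter_model`) may be
#' given as nested maps.
#'
#' @param path YAML file path.
#' @return A `sim_config`.
#' @export
read_config_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  if (!is.null(raw$intensity_model)) {
    raw$intensity_model <- lapply(raw$intensity_model, function(v) {
      v <- unlist(v)
      if (is.null(names(v))) names(v) <- c("log_mean", "log_sd")
      v
    })
  }
  do.call(sim_config, raw)
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a pipeline stage bit-for-bit:
#' the configuration snapshot, the seed, checksummed input and output file
#' lists, the package version and per-stage timings.
#'
#' @param path Manifest JSON path.
#' @param command Stage name.
#' @param config Configuration snapshot (list), may be `NULL`.
#' @param seed Seed(s) used.
#' @param inputs,outputs Character vectors of file paths.
#' @param timings Named numeric vector of elapsed seconds.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, command, config = NULL, seed = NULL,
                           inputs = character(0), outputs = character(0),
                           timings = NULL) {
  checksum <- function(files) {
    if (!length(files)) return(list())
    md5 <- tools::md5sum(files)
    mapply(function(f, h) list(path = f, md5 = unname(h)),
           files, md5, SIMPLIFY = FALSE, USE.NAMES = FALSE)
  }
  missing_out <- outputs[!file.exists(outputs)]
  if (length(missing_out)) stop("manifest lists missing output file(s): ",
                                paste(missing_out, collapse = ", "))
  man <- list(command = command,
              tool = "colonyhet",
              version = as.character(utils::packageVersion("colonyhet")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              seed = seed,
              config = config,
              inputs = checksum(inputs),
              outputs = checksum(outputs),
              timings_s = as.list(timings))
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(man)
}
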