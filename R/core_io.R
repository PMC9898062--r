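#' @title Raster and table input/output
#' @description Readers and writers for the formats the pipeline touches:
#'   multichannel 16-bit TIFFs with a JSON sidecar carrying pixel size and
#'   channel roles, float TIFFs for probability maps and shading profiles,
#'   and the tab-delimited per-fiber measurement (`_MFI`) tables.
#' @name core_io
NULL

#' Column schema of the tab-delimited measurement table
#' @export
MFI_COLUMNS <- c("Label", "Area", "Mean", "StdDev", "Mode", "Min", "Max",
                 "Median", "Circ.", "Mean_boundary", "StdDev_boundary",
                 "Mean_distance")

sidecar_path <- function(path) paste0(path, ".json")

#' Write a section image as a multichannel 16-bit TIFF
#'
#' One TIFF directory (page) per channel. Pixel size, channel roles and
#' sample identity travel in a JSON sidecar next to the TIFF (`<path>.json`);
#' an explicit sidecar beats in-file metadata, so reading the pair is
#' lossless.
#'
#' @param image a [section_image()].
#' @param path output file path (`.tif`).
#' @param overwrite if `FALSE`, refuse to replace an existing file.
#' @return `path`, invisibly.
#' @export
write_multichannel_tiff <- function(image, path, overwrite = TRUE) {
  stopifnot(inherits(image, "section_image"))
  if (!overwrite && file.exists(path)) stop("file exists and overwrite = FALSE: ", path)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir)
  pages <- lapply(seq_len(n_channels(image)), function(k) {
    round(image$pixels[, , k]) / MAX_16BIT
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  meta <- list(pixel_size_um = image$pixel_size_um,
               channel_roles = image$channel_roles,
               sample_id = image$sample_id,
               section_index = image$section_index)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multichannel 16-bit TIFF into a section image
#'
#' Metadata resolution: explicit arguments win over the JSON sidecar. A
#' missing pixel size is an error, never a silent default.
#'
#' @param path TIFF file path.
#' @param pixel_size_um pixel size in micrometres; overrides the sidecar.
#' @param channel_roles channel roles in page order; overrides the sidecar.
#'   Length must equal the number of TIFF pages.
#' @param sample_id,section_index identity overrides.
#' @return a [section_image()] with pixels identical bit-for-bit.
#' @export
read_multichannel_tiff <- function(path, pixel_size_um = NULL, channel_roles = NULL,
                                   sample_id = NULL, section_index = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]  # tolerate grey-stored-as-RGB
    round(p * MAX_16BIT)
  })
  meta <- list()
  if (file.exists(sidecar_path(path))) {
    meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  }
  if (is.null(pixel_size_um)) pixel_size_um <- meta$pixel_size_um
  if (is.null(pixel_size_um)) {
    stop("pixel size unknown for ", path,
         ": supply pixel_size_um or provide a JSON sidecar")
  }
  if (is.null(channel_roles)) channel_roles <- meta$channel_roles
  if (is.null(channel_roles)) {
    stop("channel roles unknown for ", path,
         ": supply channel_roles or provide a JSON sidecar")
  }
  if (length(channel_roles) != length(pages)) {
    stop(sprintf("channel count mismatch: file %s has %d channels but %d roles configured",
                 path, length(pages), length(channel_roles)))
  }
  pix <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) pix[, , k] <- pages[[k]]
  section_image(pix, pixel_size_um, channel_roles,
                sample_id = sample_id %||% meta$sample_id %||% "sample",
                section_index = section_index %||% meta$section_index %||% 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a single-plane real raster as a 32-bit float TIFF
#'
#' Values are stored divided by their maximum so the file stays in the
#' `[0, 1]` range the TIFF writer expects; the scale travels in the JSON
#' sidecar, so the round-trip through [read_float_tiff()] is lossless up to
#' float precision.
#'
#' @param values numeric matrix (nonnegative).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_float_tiff <- function(values, path) {
  stopifnot(is.matrix(values))
  scale <- max(values, 1e-12)
  tiff::writeTIFF(as_plain_matrix(values) / scale, path,
                  bits.per.sample = 32L, compression = "none")
  jsonlite::write_json(list(scale = scale), sidecar_path(path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a raster written by [write_float_tiff()] (or any single-page TIFF)
#'
#' Without a sidecar the values are returned as stored (in `[0, 1]`), which
#' also covers externally produced 8-bit or float probability maps: both are
#' normalised to `[0, 1]` by the TIFF reader.
#'
#' @param path TIFF path.
#' @return numeric matrix.
#' @export
read_float_tiff <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  p <- tiff::readTIFF(path, all = FALSE)
  if (length(dim(p)) == 3L) p <- p[, , 1]
  if (file.exists(sidecar_path(path))) {
    meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
    if (!is.null(meta$scale)) p <- p * meta$scale
  }
  p
}

#' Read an externally produced boundary-probability TIFF
#'
#' Accepts 8-bit (0-255) or 32-bit float (0-1) encodings; both arrive
#' normalised to `[0, 1]`.
#'
#' @param path TIFF path.
#' @return a [probability_map()] with source `"external_file"`.
#' @export
read_probability_tiff <- function(path) {
  v <- read_float_tiff(path)
  probability_map(pmin(pmax(v, 0), 1), source = "external_file")
}

#' Assemble a measurement table object
#'
#' A data frame following the `_MFI` schema ([MFI_COLUMNS]) plus parsed
#' `roi_id` / `channel` helper columns, carrying `n_channels` and the source
#' image id as attributes. One row per (ROI, channel); the row count must be
#' a multiple of `n_channels`.
#'
#' @param records data frame with at least `Label`, `Area`, `Mean` columns.
#' @param n_channels channels per ROI (5 once the classification channel is
#'   appended).
#' @param provenance source image identifier.
#' @export
mfi_table <- function(records, n_channels, provenance = "") {
  stopifnot(is.data.frame(records))
  need <- c("Label", "Area", "Mean")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records lack required column(s): ", paste(miss, collapse = ", "))
  unknown <- setdiff(names(records), c(MFI_COLUMNS, "roi_id", "channel", "sample_id"))
  if (length(unknown)) stop("unknown column(s): ", paste(unknown, collapse = ", "))
  if (nrow(records) %% n_channels != 0) {
    stop("record count ", nrow(records), " is not a multiple of n_channels ", n_channels)
  }
  if (!("roi_id" %in% names(records))) {
    parts <- split_label(records$Label)
    records$roi_id <- parts$roi_id
    records$channel <- parts$channel
  }
  structure(records, n_channels = as.integer(n_channels),
            provenance = provenance, class = c("mfi_table", "data.frame"))
}

split_label <- function(labels) {
  m <- regmatches(labels, regexec("^(.*):([0-9]+)$", labels))
  bad <- which(lengths(m) != 3L)
  if (length(bad)) {
    stop("malformed Label (expected 'ROIid:channel') in row ", bad[1], ": ", labels[bad[1]])
  }
  list(roi_id = vapply(m, `[`, "", 2L),
       channel = as.integer(vapply(m, `[`, "", 3L)))
}

#' Write a measurement table as a tab-delimited `_MFI` file
#'
#' Header row uses the canonical column names; numeric fields are printed
#' with 3 decimal places; the decimal mark is always '.'. An empty table
#' yields a header-only file.
#'
#' @param table an [mfi_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mfi_table <- function(table, path) {
  stopifnot(inherits(table, "mfi_table"))
  cols <- intersect(MFI_COLUMNS, names(table))
  out <- as.data.frame(table)[, cols, drop = FALSE]
  for (nm in setdiff(cols, "Label")) {
    out[[nm]] <- formatC(out[[nm]], format = "f", digits = 3)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, dec = ".")
  invisible(path)
}

#' Read a tab-delimited `_MFI` file
#'
#' The header must be a subset of [MFI_COLUMNS] containing at least `Label`,
#' `Area` and `Mean` (the printed example tables omit some columns). Labels
#' are split into `roi_id` and `channel`; any non-numeric measurement cell is
#' an error naming the offending line.
#'
#' @param path file path.
#' @param n_channels channels per ROI; inferred from the largest channel
#'   suffix when `NULL`.
#' @return an [mfi_table()].
#' @export
read_mfi_table <- function(path, n_channels = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  unknown <- setdiff(names(df), MFI_COLUMNS)
  if (length(unknown)) stop("unknown column(s) in ", path, ": ", paste(unknown, collapse = ", "))
  if (nrow(df) == 0) {
    empty <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(names(df))), names(df)))
    empty$Label <- character(0)
    return(mfi_table(empty, n_channels %||% 1L, provenance = path))
  }
  for (nm in setdiff(names(df), "Label")) {
    v <- suppressWarnings(as.numeric(df[[nm]]))
    bad <- which(is.na(v) & !(df[[nm]] %in% c("", "NA")))
    if (length(bad)) {
      stop(sprintf("malformed value '%s' in column %s, line %d of %s",
                   df[[nm]][bad[1]], nm, bad[1] + 1L, path))
    }
    df[[nm]] <- v
  }
  parts <- split_label(df$Label)
  df$roi_id <- parts$roi_id
  df$channel <- parts$channel
  if (is.null(n_channels)) n_channels <- max(df$channel)
  mfi_table(df, n_channels, provenance = path)
}
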