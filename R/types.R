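#' Channel roles recognised by the pipeline
#'
#' The four stained channels plus the appended pixel-classification channel.
#' `MYHC2X_OR_2B` covers the fast isoform that differs between human (2X)
#' and mouse (2B).
#'
#' @export
CHANNEL_ROLES <- c("MYHC1", "MYHC2A", "MYHC2X_OR_2B", "LAMININ", "CLASSIFICATION")

MAX_16BIT <- 65535

#' Construct a multichannel section image
#'
#' The main carrier of the pipeline: an H x W x C raster in the 16-bit
#' intensity range together with the physical pixel size and the role of
#' each channel.
#'
#' @param pixels numeric H x W x C array (a matrix is promoted to C = 1);
#'   values must lie in `[0, 65535]`.
#' @param pixel_size_um physical pixel size in micrometres; must be positive.
#' @param channel_roles character vector of length C drawn from
#'   [CHANNEL_ROLES]; at most one channel per role.
#' @param sample_id sample identifier carried into measurement tables.
#' @param section_index nonnegative integer identifying the section replicate.
#' @return an object of class `section_image`.
#' @export
section_image <- function(pixels, pixel_size_um, channel_roles,
                          sample_id = "sample", section_index = 0L) {
  if (is.matrix(pixels)) {
    pixels <- array(pixels, dim = c(dim(pixels), 1L))
  }
  stopifnot(is.array(pixels), length(dim(pixels)) == 3L)
  d <- dim(pixels)
  if (d[1] < 1 || d[2] < 1) stop("image must have H, W >= 1")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 ||
      is.na(pixel_size_um) || pixel_size_um <= 0) {
    stop("pixel_size_um must be a single positive number")
  }
  channel_roles <- as.character(channel_roles)
  if (length(channel_roles) != d[3]) {
    stop(sprintf("channel count mismatch: image has %d channels but %d roles configured",
                 d[3], length(channel_roles)))
  }
  bad <- setdiff(channel_roles, CHANNEL_ROLES)
  if (length(bad)) stop("unknown channel role(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(channel_roles)) stop("at most one channel per role")
  if (min(pixels) < 0 || max(pixels) > MAX_16BIT) {
    stop("pixel values must lie in [0, 65535]")
  }
  structure(list(pixels = pixels,
                 pixel_size_um = as.numeric(pixel_size_um),
                 channel_roles = channel_roles,
                 sample_id = as.character(sample_id),
                 section_index = as.integer(section_index)),
            class = "section_image")
}

#' @export
print.section_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("section_image: %d x %d px, %d channel(s) [%s], %.3g um/px, sample '%s' section %d\n",
              d[1], d[2], d[3], paste(x$channel_roles, collapse = ", "),
              x$pixel_size_um, x$sample_id, x$section_index))
  invisible(x)
}

#' Number of channels of a section image
#' @param image a `section_image`.
#' @export
n_channels <- function(image) dim(image$pixels)[3]

#' Extract one channel of a section image as a matrix
#'
#' @param image a `section_image`.
#' @param channel integer channel index or a role name from [CHANNEL_ROLES].
#' @return numeric H x W matrix.
#' @export
get_channel <- function(image, channel) {
  if (is.character(channel)) {
    idx <- match(channel, image$channel_roles)
    if (is.na(idx)) stop("image has no channel with role ", channel)
  } else {
    idx <- as.integer(channel)
    if (idx < 1 || idx > n_channels(image)) stop("channel index out of range")
  }
  image$pixels[, , idx]
}

#' Index of the channel holding a given role, or NA
#' @inheritParams get_channel
#' @param role a role name from [CHANNEL_ROLES].
#' @export
channel_index <- function(image, role) match(role, image$channel_roles)

#' Construct a boundary-probability map
#'
#' @param values numeric H x W matrix with entries in `[0, 1]`.
#' @param source `"internal_classifier"` or `"external_file"`.
#' @return a `probability_map` (a matrix with attributes).
#' @export
probability_map <- function(values, source = c("internal_classifier", "external_file")) {
  source <- match.arg(source)
  stopifnot(is.matrix(values))
  if (anyNA(values) || min(values) < -1e-9 || max(values) > 1 + 1e-9) {
    stop("probability values must lie in [0, 1]")
  }
  values <- pmin(pmax(values, 0), 1)
  structure(values, source = source, class = c("probability_map", "matrix", "array"))
}

#' Construct a tissue mask
#' @param mask logical H x W matrix (TRUE = tissue).
#' @param edits_applied count of polygon edits already applied.
#' @export
tissue_mask <- function(mask, edits_applied = 0L) {
  stopifnot(is.matrix(mask))
  mask <- mask > 0
  structure(mask, edits_applied = as.integer(edits_applied),
            class = c("tissue_mask", "matrix", "array"))
}

#' Construct a label map
#'
#' Nonnegative integer raster; 0 is background, positive values identify
#' fiber regions of interest.
#' @param labels integer H x W matrix.
#' @export
label_map <- function(labels) {
  stopifnot(is.matrix(labels))
  if (min(labels) < 0) stop("labels must be nonnegative")
  storage.mode(labels) <- "integer"
  structure(labels, class = c("label_map", "matrix", "array"))
}

# strip classes/attributes down to a plain matrix
as_plain_matrix <- function(x) {
  matrix(as.vector(x), nrow = nrow(x), ncol = ncol(x))
}
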