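#' @title Tissue mask, scripted edits, masked laminin, edge distance
#' @description Automatic tissue-mask generation from the laminin channel,
#'   reproducible polygon-script editing in place of interactive correction,
#'   the feathered masked-laminin image fed to the pixel classifier, and the
#'   Euclidean distance-to-tissue-edge map used by the measurement stage.
#' @name tissue_mask_module
NULL

#' Automatically generate a tissue mask from the laminin channel
#'
#' Gaussian-blurs the laminin channel (laminin outlines every fiber
#' regardless of type, so it traces all tissue), applies an Otsu threshold,
#' fills holes, removes small objects, and keeps only connected components
#' at least `keep_frac` of the largest.
#'
#' @param image a [section_image()] with a LAMININ channel.
#' @param sigma_px blur sigma in pixels.
#' @param min_area_px minimum object area kept (px^2).
#' @param keep_frac components smaller than this fraction of the largest
#'   are dropped.
#' @return a [tissue_mask()].
#' @export
auto_tissue_mask <- function(image, sigma_px = 10, min_area_px = 2000,
                             keep_frac = 0.1) {
  stopifnot(inherits(image, "section_image"))
  if (is.na(channel_index(image, "LAMININ"))) stop("image has no LAMININ channel")
  lam <- get_channel(image, "LAMININ")
  if (max(lam) == min(lam)) stop("no tissue found: blank laminin channel")
  g <- gaussian_blur(lam, sigma_px) / MAX_16BIT
  th <- EBImage::otsu(EBImage::Image(g), range = c(0, 1))
  bw <- g > th
  if (!any(bw)) stop("no tissue found")
  bw <- as_plain_matrix(EBImage::fillHull(bw * 1)) > 0
  lab <- as_plain_matrix(EBImage::bwlabel(bw * 1))
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area_px & sizes >= keep_frac * max(sizes))
  if (length(keep) == 0) stop("no tissue found")
  tissue_mask(matrix(lab %in% keep, nrow(lam), ncol(lam)))
}

#' A single scripted mask edit
#'
#' @param op `"add"` or `"remove"`.
#' @param polygon matrix/data frame of vertices, columns (x = col, y = row)
#'   in 0-based pixel coordinates; >= 3 vertices, inside the image bounds.
#' @export
polygon_edit <- function(op = c("add", "remove"), polygon) {
  op <- match.arg(op)
  polygon <- as.matrix(polygon)
  if (nrow(polygon) < 3) stop("polygon needs at least 3 vertices")
  list(op = op, polygon = polygon)
}

#' Apply an ordered list of polygon edits to a mask
#'
#' Replaces the interactive mask correction with a reproducible script:
#' edits are applied in order; `add` sets the covered pixels to tissue,
#' `remove` clears them. Coverage follows the even-odd rule with
#' pixel-center inclusion, so each edit is idempotent.
#'
#' @param mask a [tissue_mask()].
#' @param edits list of [polygon_edit()]s.
#' @return edited [tissue_mask()] with `edits_applied` incremented.
#' @export
apply_mask_edits <- function(mask, edits) {
  stopifnot(inherits(mask, "tissue_mask"))
  h <- nrow(mask); w <- ncol(mask)
  m <- as_plain_matrix(mask) > 0
  for (e in edits) {
    poly <- e$polygon
    if (min(poly[, 1]) < 0 || max(poly[, 1]) > w ||
        min(poly[, 2]) < 0 || max(poly[, 2]) > h) {
      stop("polygon vertices outside image bounds")
    }
    cov <- polygon_pixels(poly, h, w)
    m[cov] <- (e$op == "add")
  }
  tissue_mask(m, edits_applied = attr(mask, "edits_applied") + length(edits))
}

#' Feathered masked copy of the laminin channel
#'
#' Blurring the binary mask avoids a hard edge artifact: with
#' `m = gaussian_blur(mask, sigma)` the output is
#' `m * laminin + (1 - m) * median(laminin outside the mask)`, so pixels
#' deep inside tissue are untouched and pixels far outside sit exactly at
#' the outside median.
#'
#' @param image a [section_image()] with a LAMININ channel.
#' @param mask a [tissue_mask()].
#' @param sigma_px feather width (Gaussian sigma, default 4 px).
#' @return numeric H x W matrix on the 16-bit scale.
#' @export
masked_laminin <- function(image, mask, sigma_px = 4) {
  stopifnot(inherits(image, "section_image"), sigma_px > 0)
  lam <- get_channel(image, "LAMININ")
  if (!all(dim(mask) == dim(lam))) stop("mask shape does not match image")
  mm <- as_plain_matrix(mask) > 0
  med <- if (any(!mm)) stats::median(lam[!mm]) else stats::median(lam)
  if (all(mm)) return(lam)
  m <- gaussian_blur(mm * 1, sigma_px)
  m <- pmin(pmax(m, 0), 1)
  round(m * lam + (1 - m) * med)
}

#' Euclidean distance of each tissue pixel to the tissue edge
#'
#' Distance (in micrometres) from every foreground pixel to the nearest
#' background pixel; pixels beyond the image frame count as background, and
#' the map is zero outside the mask.
#'
#' @param mask a [tissue_mask()].
#' @param pixel_size_um pixel size in micrometres.
#' @return numeric H x W matrix (um).
#' @export
edge_distance_map <- function(mask, pixel_size_um) {
  stopifnot(pixel_size_um > 0)
  m <- as_plain_matrix(mask) > 0
  if (!any(m)) stop("empty mask")
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(0, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- m * 1
  d <- as_plain_matrix(EBImage::distmap(pad, metric = "euclidean"))
  d[2:(h + 1), 2:(w + 1)] * pixel_size_um
}
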