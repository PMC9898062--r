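#' @title Per-fiber, per-channel measurement table
#' @description Computes the tab-delimited measurement schema: per ROI and
#'   channel the area, interior intensity statistics, circularity, the
#'   statistics over a 3-pixel boundary strip, and the mean distance to the
#'   tissue edge. The classification (boundary-probability) channel is
#'   appended as channel 5 on a 0-255 scale so that segmentation certainty
#'   can be assessed from the same table.
#' @name measurement
NULL

#' Append the pixel-classification channel to a section image
#'
#' Channel values are `round(probability * 255)` (half away from zero), so a
#' well-segmented fiber shows ~high values on its boundary strip and low
#' values inside.
#'
#' @param image a [section_image()] without a CLASSIFICATION channel.
#' @param prob a [probability_map()] of matching shape.
#' @return a [section_image()] with one extra channel of role
#'   CLASSIFICATION.
#' @export
append_classification_channel <- function(image, prob) {
  stopifnot(inherits(image, "section_image"))
  if (!is.na(channel_index(image, "CLASSIFICATION"))) {
    stop("image already has a CLASSIFICATION channel")
  }
  p <- as_plain_matrix(prob)
  d <- dim(image$pixels)
  if (!all(dim(p) == d[1:2])) stop("probability map shape does not match image")
  ch5 <- floor(p * 255 + 0.5)
  pix <- array(0, dim = c(d[1], d[2], d[3] + 1))
  pix[, , seq_len(d[3])] <- image$pixels
  pix[, , d[3] + 1] <- ch5
  section_image(pix, image$pixel_size_um, c(image$channel_roles, "CLASSIFICATION"),
                image$sample_id, image$section_index)
}

roi_bbox <- function(lab, id, margin, h, w) {
  px <- which(lab == id)
  if (length(px) == 0) stop("unknown roi_id: ", id)
  r <- (px - 1) %% h + 1; c <- (px - 1) %/% h + 1
  list(r0 = max(1, min(r) - margin), r1 = min(h, max(r) + margin),
       c0 = max(1, min(c) - margin), c1 = min(w, max(c) + margin))
}

#' Pixels of the boundary strip around an ROI
#'
#' The Euclidean dilation of the ROI by a disk of radius `width_px`, minus
#' the ROI itself, clipped to the image bounds. Computed from the exact
#' Euclidean distance transform, so the strip is
#' `{pixel : 0 < dist(pixel, ROI) <= width_px}`.
#'
#' @param labels a [label_map()].
#' @param roi_id positive label present in `labels`.
#' @param width_px strip width (>= 1).
#' @return two-column matrix of (row, col) pixel coordinates.
#' @export
boundary_strip <- function(labels, roi_id, width_px = 3) {
  if (width_px < 1) stop("width_px must be >= 1")
  lab <- as_plain_matrix(labels)
  h <- nrow(lab); w <- ncol(lab)
  bb <- roi_bbox(lab, roi_id, width_px + 1L, h, w)
  sub <- lab[bb$r0:bb$r1, bb$c0:bb$c1, drop = FALSE]
  roi <- sub == roi_id
  d <- as_plain_matrix(EBImage::distmap((!roi) * 1, metric = "euclidean"))
  strip <- !roi & d <= width_px
  idx <- which(strip)
  cbind(row = (idx - 1) %% nrow(sub) + bb$r0,
        col = (idx - 1) %/% nrow(sub) + bb$c0)
}

# Moore-neighbour tracing of the outer contour; returns counts of axial and
# diagonal chain moves. mask must contain a single 4-connected component.
trace_chain <- function(mask) {
  npx <- sum(mask)
  if (npx <= 1) return(c(axial = 0, diagonal = 0))
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- mask
  # clockwise neighbour offsets starting north (0-based direction index)
  dr <- c(-1, -1, 0, 1, 1, 1, 0, -1)
  dc <- c(0, 1, 1, 1, 0, -1, -1, -1)
  idx <- which(pad)
  rr <- (idx - 1) %% (h + 2) + 1
  cc <- (idx - 1) %/% (h + 2) + 1
  o <- order(rr, cc)
  sr <- rr[o[1]]; sc <- cc[o[1]]          # topmost-then-leftmost pixel
  cur <- c(sr, sc)
  back <- c(sr, sc - 1)                   # background cell west of start
  back0 <- back
  n_ax <- 0L; n_di <- 0L
  max_steps <- 8L * (npx + 4L)
  for (step in seq_len(max_steps)) {
    d0 <- which(dr == back[1] - cur[1] & dc == back[2] - cur[2]) - 1L
    moved <- FALSE
    for (k in 1:8) {
      j <- (d0 + k) %% 8L
      cand <- cur + c(dr[j + 1L], dc[j + 1L])
      if (pad[cand[1], cand[2]]) {
        if (dr[j + 1L] == 0 || dc[j + 1L] == 0) n_ax <- n_ax + 1L
        else n_di <- n_di + 1L
        if (k > 1) {
          jp <- (d0 + k - 1L) %% 8L
          back <- cur + c(dr[jp + 1L], dc[jp + 1L])
        }                                 # else keep previous backtrack cell
        cur <- cand
        moved <- TRUE
        break
      }
    }
    if (!moved) break                     # isolated pixel
    if (cur[1] == sr && cur[2] == sc && all(back == back0)) break
  }
  c(axial = n_ax, diagonal = n_di)
}

#' Circularity of an ROI
#'
#' `4 * pi * Area / Perimeter^2`, capped at 1. Area is the pixel count; the
#' perimeter is the corner-corrected chain-code length of the outer contour
#' (Kulpa weights 0.948 per axial and 1.340 per diagonal move), which is
#' unbiased enough that a rasterised disk scores ~1 while elongated shapes
#' fall well below 0.5. Holes are filled before tracing, so only the outer
#' outline counts. Dimensionless, so the pixel size cancels.
#'
#' @param roi_mask logical matrix covering the ROI (TRUE = ROI pixel).
#' @return circularity in (0, 1].
#' @export
circularity <- function(roi_mask) {
  stopifnot(is.matrix(roi_mask))
  roi_mask <- roi_mask > 0
  a <- sum(roi_mask)
  if (a == 0) stop("empty ROI")
  if (a == 1) return(1)
  filled <- as_plain_matrix(EBImage::fillHull(roi_mask * 1)) > 0
  ch <- trace_chain(filled)
  per <- 0.948 * ch["axial"] + 1.340 * ch["diagonal"]
  if (per <= 0) return(1)
  min(1, 4 * pi * sum(filled) / per^2)
}

int_mode <- function(v) {
  # mode of the 16-bit integer histogram; ties -> smallest value
  t <- tabulate(round(v) + 1L)
  which.max(t) - 1L
}

#' Measure all fibers of a section
#'
#' One record per (ROI, channel) following the `_MFI` schema: `Area` is the
#' interior pixel count times the squared pixel size (um^2); `Mean`,
#' `StdDev`, `Mode`, `Min`, `Max`, `Median` are interior statistics of the
#' channel; `Circ.` the shape circularity; `Mean_boundary` /
#' `StdDev_boundary` the statistics over the outer boundary strip; and
#' `Mean_distance` the mean distance of interior pixels to the tissue edge
#' (um). Area, circularity and mean distance are shape properties and are
#' identical across the channel rows of one ROI.
#'
#' @param image a [section_image()] including the CLASSIFICATION channel
#'   (see [append_classification_channel()]); its absence is an error since
#'   the segmentation-certainty metrics would be undefined.
#' @param labels a [label_map()].
#' @param distmap_um edge-distance raster from [edge_distance_map()].
#' @param strip_width_px boundary strip width (default 3).
#' @return an [mfi_table()] with `n_channels = ` number of image channels.
#' @export
measure_section <- function(image, labels, distmap_um, strip_width_px = 3) {
  stopifnot(inherits(image, "section_image"))
  if (is.na(channel_index(image, "CLASSIFICATION"))) {
    stop("image lacks a CLASSIFICATION channel; segmentation certainty would be undefined")
  }
  lab <- as_plain_matrix(labels)
  d <- dim(image$pixels)
  if (!all(dim(lab) == d[1:2])) stop("label map shape does not match image")
  if (!all(dim(distmap_um) == d[1:2])) stop("distance map shape does not match image")
  ids <- sort(unique(lab[lab > 0]))
  if (length(ids) == 0) stop("no ROIs to measure")
  nc <- d[3]
  ps <- image$pixel_size_um
  h <- d[1]

  fg <- lab > 0
  f <- factor(lab[fg], levels = ids)
  area <- as.numeric(table(f)) * ps^2
  mean_dist <- as.numeric(tapply(distmap_um[fg], f, mean))

  circ <- numeric(length(ids))
  strips <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    bb <- roi_bbox(lab, ids[i], strip_width_px + 1L, h, d[2])
    sub <- lab[bb$r0:bb$r1, bb$c0:bb$c1, drop = FALSE]
    roi <- sub == ids[i]
    circ[i] <- circularity(roi)
    dd <- as_plain_matrix(EBImage::distmap((!roi) * 1, metric = "euclidean"))
    sidx <- which(!roi & dd <= strip_width_px)
    strips[[i]] <- cbind((sidx - 1) %% nrow(sub) + bb$r0,
                         (sidx - 1) %/% nrow(sub) + bb$c0)
  }

  recs <- vector("list", nc)
  for (ch in seq_len(nc)) {
    v <- image$pixels[, , ch]
    vi <- v[fg]
    mb <- vapply(strips, function(s) mean(v[s]), 0)
    sb <- vapply(strips, function(s) stats::sd(v[s]), 0)
    sb[is.na(sb)] <- 0
    sdv <- as.numeric(tapply(vi, f, stats::sd)); sdv[is.na(sdv)] <- 0
    recs[[ch]] <- data.frame(
      Label = sprintf("%04d:%d", ids, ch),
      Area = area,
      Mean = as.numeric(tapply(vi, f, mean)),
      StdDev = sdv,
      Mode = as.numeric(tapply(vi, f, int_mode)),
      Min = as.numeric(tapply(vi, f, min)),
      Max = as.numeric(tapply(vi, f, max)),
      Median = as.numeric(tapply(vi, f, stats::median)),
      `Circ.` = circ,
      Mean_boundary = mb,
      StdDev_boundary = sb,
      Mean_distance = mean_dist,
      check.names = FALSE, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, recs)
  # interleave so the channel rows of each ROI are adjacent, as exported
  out <- out[order(out$Label), , drop = FALSE]
  rownames(out) <- NULL
  mfi_table(out, nc, provenance = image$sample_id)
}
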