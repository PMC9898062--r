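#' @title Fiber segmentation from the boundary-probability map
#' @description Converts the per-pixel boundary probability into individual
#'   myofiber regions of interest: thresholded boundary ridges separate the
#'   tissue into seed components, a seeded watershed on the smoothed
#'   probability grows the seeds back together, and the ridge pixels remain
#'   unassigned so that fiber interiors exclude the laminin line.
#' @name segmentation
NULL

#' Segmentation parameters
#'
#' @param prob_threshold boundary threshold on the smoothed probability,
#'   strictly inside (0, 1).
#' @param smooth_sigma_px Gaussian smoothing of the probability map (px).
#' @param min_seed_area_px minimum seed-component area (px^2).
#' @param border_policy `"exclude"` drops frame-touching fibers during
#'   [filter_labels()]; `"keep"` retains them.
#' @export
segmentation_params <- function(prob_threshold = 0.5, smooth_sigma_px = 1.0,
                                min_seed_area_px = 9, border_policy = c("exclude", "keep")) {
  if (prob_threshold <= 0 || prob_threshold >= 1) {
    stop("prob_threshold must lie strictly inside (0, 1)")
  }
  list(prob_threshold = prob_threshold, smooth_sigma_px = smooth_sigma_px,
       min_seed_area_px = min_seed_area_px,
       border_policy = match.arg(border_policy))
}

#' Segment myofibers from a boundary-probability map
#'
#' Boundary ridge = smoothed probability >= threshold. Seeds are the
#' 4-connected components of tissue minus ridge with area >=
#' `min_seed_area_px`; a seeded watershed (intensity-guided propagation on
#' the smoothed probability) floods the non-ridge tissue from the seeds.
#' Ridge pixels stay background, which is what makes the downstream
#' classification-channel certainty metrics discriminative.
#'
#' @param prob a [probability_map()].
#' @param mask a [tissue_mask()] of the same shape.
#' @param params [segmentation_params()].
#' @return a [label_map()]; labels are contiguous 1..N.
#' @export
segment_fibers <- function(prob, mask, params = segmentation_params()) {
  m <- as_plain_matrix(mask) > 0
  p <- as_plain_matrix(prob)
  if (!all(dim(p) == dim(m))) stop("probability map and mask shapes differ")
  if (!any(m)) stop("empty tissue mask")
  ps <- if (params$smooth_sigma_px > 0) gaussian_blur(p, params$smooth_sigma_px) else p
  ridge <- ps >= params$prob_threshold
  interior <- m & !ridge
  seeds <- as_plain_matrix(EBImage::bwlabel(interior * 1))
  sizes <- tabulate(seeds[seeds > 0])
  drop <- which(sizes < params$min_seed_area_px)
  if (length(drop)) seeds[seeds %in% drop] <- 0L
  if (!any(seeds > 0)) return(label_map(matrix(0L, nrow(p), ncol(p))))
  # relabel seeds contiguously
  ids <- sort(unique(seeds[seeds > 0]))
  remap <- integer(max(ids)); remap[ids] <- seq_along(ids)
  seeds[seeds > 0] <- remap[seeds[seeds > 0]]
  lab <- EBImage::propagate(EBImage::Image(ps), seeds, mask = interior)
  label_map(as_plain_matrix(EBImage::imageData(lab)))
}

#' Pre-measurement label cleanup
#'
#' Fills holes within each fiber, removes components below `min_area_px`,
#' optionally removes fibers touching the image frame, and relabels
#' contiguously (in increasing original-id order).
#'
#' @param labels a [label_map()].
#' @param min_area_px minimum fiber area in pixels.
#' @param border_policy `"exclude"` or `"keep"`.
#' @return filtered [label_map()].
#' @export
filter_labels <- function(labels, min_area_px = 9,
                          border_policy = c("exclude", "keep")) {
  border_policy <- match.arg(border_policy)
  lab <- as_plain_matrix(labels)
  storage.mode(lab) <- "integer"
  if (any(lab > 0)) {
    lab <- as_plain_matrix(EBImage::fillHull(lab))
  }
  if (any(lab > 0)) {
    sizes <- tabulate(lab[lab > 0])
    drop <- which(sizes > 0 & sizes < min_area_px)
    if (border_policy == "exclude") {
      h <- nrow(lab); w <- ncol(lab)
      touching <- unique(c(lab[1, ], lab[h, ], lab[, 1], lab[, w]))
      drop <- union(drop, touching[touching > 0])
    }
    if (length(drop)) lab[lab %in% drop] <- 0L
  }
  ids <- sort(unique(lab[lab > 0]))
  if (length(ids)) {
    remap <- integer(max(ids)); remap[ids] <- seq_along(ids)
    lab[lab > 0] <- remap[lab[lab > 0]]
  }
  label_map(lab)
}
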