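#' @title Downsampling and retrospective shading correction
#' @description Block-average downsampling to the 1-5 um/px working
#'   resolution, and an in-library shading estimator: each channel is
#'   heavily smoothed, normalised to mean 1 and floored, the per-slide
#'   profiles are combined by a per-pixel median, and images are corrected
#'   by division.
#' @name preprocess
NULL

#' Construct a shading profile
#' @param values strictly positive H x W matrix, mean ~1.
#' @param channel_index channel this profile corrects.
#' @export
shading_profile <- function(values, channel_index = 1L) {
  stopifnot(is.matrix(values))
  if (min(values) <= 0) stop("shading profile must be strictly positive")
  structure(values, channel_index = as.integer(channel_index),
            class = c("shading_profile", "matrix", "array"))
}

block_mean <- function(m, factor) {
  rg <- ceiling(seq_len(nrow(m)) / factor)
  cg <- ceiling(seq_len(ncol(m)) / factor)
  s <- rowsum(m, rg, reorder = TRUE)
  s <- t(rowsum(t(s), cg, reorder = TRUE))
  cnt <- outer(tabulate(rg), tabulate(cg))
  s / cnt
}

#' Downsample a section image by block averaging
#'
#' Each output pixel is the arithmetic mean of its `factor` x `factor`
#' block; trailing partial blocks are averaged over the pixels available, so
#' tissue at the image edge is preserved. The pixel size is multiplied by
#' `factor`; a warning is issued if the resulting pixel size leaves the
#' 1-5 um working range the segmentation is designed for.
#'
#' @param image a [section_image()].
#' @param factor integer >= 1 (4 reproduces the standard conversion,
#'   0.65 um/px -> 2.6 um/px).
#' @return downsampled [section_image()].
#' @export
downsample_by_averaging <- function(image, factor) {
  stopifnot(inherits(image, "section_image"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1) stop("factor must be a positive integer")
  d <- dim(image$pixels)
  if (d[1] < factor || d[2] < factor) stop("image smaller than downsampling factor")
  planes <- lapply(seq_len(d[3]), function(k) block_mean(image$pixels[, , k], factor))
  pix <- array(0, dim = c(dim(planes[[1]]), d[3]))
  for (k in seq_len(d[3])) pix[, , k] <- planes[[k]]
  ps <- image$pixel_size_um * factor
  if (ps < 1 || ps > 5) {
    warning(sprintf("effective pixel size %.3g um is outside the 1-5 um working range", ps))
  }
  section_image(pix, ps, image$channel_roles, image$sample_id, image$section_index)
}

#' Estimate a per-channel shading profile from one image
#'
#' Shading is low-frequency relative to fibers, so heavy Gaussian smoothing
#' (default sigma `min(H, W)/8`) isolates it. Two refinements over a plain
#' blur: the smoothing is intensity-weighted (`blur(x^2) / blur(x)`, a
#' normalised convolution), so dark off-tissue background does not drag the
#' profile down near the tissue border; and the estimate is refined once on
#' the corrected image, recovering the modulation the blur attenuates. On a
#' flat image the profile is exactly 1. The result is normalised to mean 1
#' and floored at 0.05 to keep the later division stable.
#'
#' @param image a [section_image()].
#' @param channel channel index or role name.
#' @param smooth_sigma_px blur sigma in pixels (> 0).
#' @return a [shading_profile()].
#' @export
estimate_shading_profile <- function(image, channel,
                                     smooth_sigma_px = min(dim(image$pixels)[1:2]) / 8) {
  stopifnot(inherits(image, "section_image"), smooth_sigma_px > 0)
  ch <- get_channel(image, channel)
  if (max(ch) == 0) stop("cannot estimate shading from an all-zero channel")
  wblur <- function(x) {
    e <- gaussian_blur(x * x, smooth_sigma_px) /
      pmax(gaussian_blur(x, smooth_sigma_px), 1e-9)
    e <- e / mean(e)
    e <- pmax(e, 0.05)
    e / mean(e)
  }
  e1 <- wblur(ch)
  sm <- e1 * wblur(ch / e1)
  sm <- sm / mean(sm)
  sm <- pmax(sm, 0.05)
  sm <- sm / mean(sm)
  idx <- if (is.character(channel)) channel_index(image, channel) else as.integer(channel)
  shading_profile(sm, idx)
}

#' Median shading profile across slides
#'
#' Per-pixel median of >= 1 same-shape profiles, renormalised to mean 1.
#'
#' @param profiles list of [shading_profile()] objects.
#' @return a [shading_profile()].
#' @export
median_shading_profile <- function(profiles) {
  if (length(profiles) < 1) stop("need at least one profile")
  dims <- vapply(profiles, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("profiles have mismatched shapes")
  }
  stack <- array(unlist(lapply(profiles, as_plain_matrix)),
                 dim = c(dims[1, 1], dims[2, 1], length(profiles)))
  med <- apply(stack, c(1, 2), stats::median)
  med <- med / mean(med)
  shading_profile(pmax(med, 0.05), attr(profiles[[1]], "channel_index"))
}

#' Correct a section image by dividing out shading profiles
#'
#' @param image a [section_image()].
#' @param profiles list of [shading_profile()] objects, one per channel in
#'   channel order (or fewer, matched by their `channel_index` attribute);
#'   a channel without a profile is an error.
#' @return corrected [section_image()], rounded and clipped to 16-bit.
#' @export
apply_shading_correction <- function(image, profiles) {
  stopifnot(inherits(image, "section_image"))
  if (inherits(profiles, "shading_profile")) profiles <- list(profiles)
  d <- dim(image$pixels)
  idx <- vapply(profiles, function(p) attr(p, "channel_index") %||% NA_integer_, 1L)
  if (anyNA(idx)) idx <- seq_along(profiles)
  missing <- setdiff(seq_len(d[3]), idx)
  if (length(missing)) {
    stop("missing shading profile for channel(s): ", paste(missing, collapse = ", "))
  }
  pix <- image$pixels
  for (j in seq_along(profiles)) {
    p <- profiles[[j]]
    if (!all(dim(p) == d[1:2])) stop("profile shape does not match image")
    pix[, , idx[j]] <- pix[, , idx[j]] / as_plain_matrix(p)
  }
  pix <- round(pmin(pmax(pix, 0), MAX_16BIT))
  section_image(pix, image$pixel_size_um, image$channel_roles,
                image$sample_id, image$section_index)
}
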