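# shared raster helpers

# Gaussian blur with replicated edges; thin wrapper fixing the boundary
# behaviour (EBImage's default circular wrap would leak opposite edges into
# shading and mask estimates).
gaussian_blur <- function(m, sigma) {
  stopifnot(sigma > 0)
  r <- max(3, 2 * ceiling(3 * sigma) + 1)
  # filter radius must stay below half the image extent for filter2
  r <- min(r, 2 * floor((min(dim(m)) - 1) / 2) - 1)
  if (r < 3) r <- 3
  out <- EBImage::gblur(EBImage::Image(as_plain_matrix(m)), sigma = sigma,
                        radius = r, boundary = "replicate")
  as_plain_matrix(EBImage::imageData(out))
}

# Pixels covered by a polygon under the even-odd rule with pixel-center
# inclusion. Vertices are (x = col, y = row) in 0-based coordinates; pixel
# (r, c) (1-based) has center (c - 0.5, r - 0.5). Returns a logical H x W
# matrix. The half-open convention means a vertical edge at integer x
# belongs to the pixel on its right.
polygon_pixels <- function(poly, h, w) {
  poly <- as.matrix(poly)
  if (nrow(poly) < 3) stop("polygon needs at least 3 vertices")
  px <- poly[, 1]; py <- poly[, 2]
  out <- matrix(FALSE, h, w)
  rmin <- max(1, floor(min(py) + 0.5)); rmax <- min(h, ceiling(max(py) + 0.5))
  cmin <- max(1, floor(min(px) + 0.5)); cmax <- min(w, ceiling(max(px) + 0.5))
  if (rmin > rmax || cmin > cmax) return(out)
  n <- length(px)
  j <- c(n, seq_len(n - 1))
  for (r in rmin:rmax) {
    yc <- r - 0.5
    # crossing-number test against each edge, vectorised over columns
    crosses <- (py > yc) != (py[j] > yc)
    if (!any(crosses)) next
    xi <- px[crosses] + (yc - py[crosses]) *
      (px[j][crosses] - px[crosses]) / (py[j][crosses] - py[crosses])
    xc <- (cmin:cmax) - 0.5
    cnt <- colSums(outer(xi, xc, FUN = ">"))
    out[r, (cmin:cmax)[cnt %% 2 == 1]] <- TRUE
  }
  out
}

# Match predicted labels to truth labels by intersection-over-union.
# Returns a data frame with one row per truth label: its best-overlapping
# predicted label and the IoU. Pairs with IoU > 0.5 are necessarily
# one-to-one.
match_labels <- function(pred, truth) {
  t_ids <- sort(unique(truth[truth > 0]))
  p_ids <- sort(unique(pred[pred > 0]))
  if (length(t_ids) == 0 || length(p_ids) == 0) {
    return(data.frame(truth_id = integer(0), pred_id = integer(0), iou = numeric(0)))
  }
  sel <- truth > 0 & pred > 0
  tab <- table(factor(truth[sel], levels = t_ids),
               factor(pred[sel], levels = p_ids))
  tsz <- tabulate(truth[truth > 0], nbins = max(t_ids))[t_ids]
  psz <- tabulate(pred[pred > 0], nbins = max(p_ids))[p_ids]
  res <- lapply(seq_along(t_ids), function(i) {
    j <- which.max(tab[i, ])
    inter <- as.numeric(tab[i, j])
    data.frame(truth_id = t_ids[i], pred_id = p_ids[j],
               iou = inter / (tsz[i] + psz[j] - inter))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
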