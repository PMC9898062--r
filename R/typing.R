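#' @title Data-driven myofiber typing by mean-shift clustering
#' @description The mean intensities of the three myosin heavy chain
#'   isoform channels are scaled per sample (uncentered), log-transformed,
#'   pooled across samples, and clustered with Gaussian-kernel mean shift.
#'   Clusters holding under ~2% of fibers are pruned, the remainder are
#'   named after their dominant isoform (with hybrid and low-intensity
#'   tags), and per-sample type compositions are tabulated.
#' @name typing
NULL

#' Typing configuration
#'
#' @param bandwidth_h mean-shift kernel bandwidth; with `scale_range = TRUE`
#'   it is a fraction of each coordinate's range, and values in
#'   `[0.01, 0.05]` are the useful exploration window (smaller h -> more,
#'   smaller clusters).
#' @param min_cluster_prop clusters below this fiber proportion are pruned
#'   (default 0.02).
#' @param zero_floor positive floor applied before the log transform.
#' @param converge_tol per-point convergence tolerance; default
#'   `1e-6 * data diameter`, resolved at run time.
#' @param max_iter maximum mean-shift iterations per point.
#' @param mode_merge_radius converged positions closer than this merge into
#'   one mode; default `bandwidth_h / 2`.
#' @param scale_range divide each coordinate by its range before shifting
#'   (the convention of the original clustering implementation), so `h` is
#'   resolution-independent.
#' @param hybrid_margin log-units margin under which the top two isoform
#'   means tie into a hybrid label.
#' @param low_quantile clusters whose three isoform means all fall below
#'   this quantile of the pooled transformed values are tagged low-MyHC.
#' @export
typing_config <- function(bandwidth_h = 0.03, min_cluster_prop = 0.02,
                          zero_floor = 1e-4, converge_tol = NULL,
                          max_iter = 500, mode_merge_radius = NULL,
                          scale_range = TRUE, hybrid_margin = 0.2,
                          low_quantile = 0.1) {
  if (bandwidth_h <= 0) stop("bandwidth_h must be positive")
  if (min_cluster_prop < 0 || min_cluster_prop >= 1) {
    stop("min_cluster_prop must lie in [0, 1)")
  }
  list(bandwidth_h = bandwidth_h, min_cluster_prop = min_cluster_prop,
       zero_floor = zero_floor, converge_tol = converge_tol,
       max_iter = max_iter,
       mode_merge_radius = mode_merge_radius %||% (bandwidth_h / 2),
       scale_range = scale_range, hybrid_margin = hybrid_margin,
       low_quantile = low_quantile)
}

#' Scale isoform intensities per sample without centering
#'
#' Within each sample, every isoform column is divided by its uncentered
#' root mean square `sqrt(mean(x^2))`, so per-sample staining strength
#' cancels while zero stays zero. A zero-RMS column is an error naming the
#' sample and channel.
#'
#' @param mfi n x 3 nonnegative matrix (MyHC1, MyHC2A, MyHC2X/2B means).
#' @param sample_of sample id per fiber (length n).
#' @return scaled n x 3 matrix.
#' @export
scale_per_sample <- function(mfi, sample_of) {
  mfi <- as.matrix(mfi)
  if (any(mfi < 0)) stop("intensities must be nonnegative")
  if (length(sample_of) != nrow(mfi)) stop("sample_of must have one entry per fiber")
  out <- mfi
  for (s in unique(sample_of)) {
    sel <- sample_of == s
    rms <- sqrt(colMeans(mfi[sel, , drop = FALSE]^2))
    zero <- which(rms == 0)
    if (length(zero)) {
      stop(sprintf("sample '%s', channel %d: zero intensity throughout, cannot scale",
                   s, zero[1]))
    }
    out[sel, ] <- sweep(mfi[sel, , drop = FALSE], 2, rms, "/")
  }
  out
}

#' Natural-log transform with a zero floor
#'
#' @param scaled nonnegative matrix.
#' @param zero_floor values below this are lifted to it before `log`.
#' @return `log(pmax(scaled, zero_floor))`.
#' @export
log_transform <- function(scaled, zero_floor = 1e-4) {
  stopifnot(zero_floor > 0)
  log(pmax(as.matrix(scaled), zero_floor))
}

#' Gaussian-kernel mean-shift clustering
#'
#' Every point climbs the kernel density estimate: `x <- sum_i w_i x_i /
#' sum_i w_i` with `w_i = exp(-||x - x_i||^2 / (2 h^2))`, iterated until the
#' step is below the tolerance or `max_iter` is hit. Converged positions
#' within `mode_merge_radius` of an existing mode are merged; each point is
#' labelled by its mode. With `scale_range = TRUE` (default) coordinates
#' are divided by their ranges first and modes are mapped back afterwards.
#'
#' @param points n x d numeric matrix (finite).
#' @param cfg a [typing_config()].
#' @return list with `modes` (k x d, data scale), `labels` (n), `n_iter`.
#' @export
mean_shift <- function(points, cfg = typing_config()) {
  x <- as.matrix(points)
  if (!all(is.finite(x))) stop("points must be finite")
  n <- nrow(x); d <- ncol(x)
  if (n == 1) return(list(modes = x, labels = 1L, n_iter = 0L))
  scl <- rep(1, d)
  if (cfg$scale_range) {
    scl <- apply(x, 2, function(v) diff(range(v)))
    scl[scl == 0] <- 1
  }
  xs <- sweep(x, 2, scl, "/")
  diam <- sqrt(sum(apply(xs, 2, function(v) diff(range(v)))^2))
  tol <- cfg$converge_tol %||% (1e-6 * max(diam, 1e-12))
  h2 <- 2 * cfg$bandwidth_h^2
  y <- xs
  active <- rep(TRUE, n)
  sq <- rowSums(xs^2)
  iter <- 0L
  while (any(active) && iter < cfg$max_iter) {
    iter <- iter + 1L
    ya <- y[active, , drop = FALSE]
    # squared distances from active positions to all data points
    d2 <- outer(rowSums(ya^2), sq, "+") - 2 * tcrossprod(ya, xs)
    w <- exp(-pmax(d2, 0) / h2)
    ynew <- (w %*% xs) / rowSums(w)
    step <- sqrt(rowSums((ynew - ya)^2))
    y[active, ] <- ynew
    done <- step < tol
    active[active] <- !done
  }
  # merge converged positions into modes (greedy, in point order)
  modes <- matrix(numeric(0), 0, d)
  labels <- integer(n)
  for (i in seq_len(n)) {
    if (nrow(modes) > 0) {
      dist <- sqrt(rowSums(sweep(modes, 2, y[i, ])^2))
      j <- which.min(dist)
      if (dist[j] <= cfg$mode_merge_radius) {
        labels[i] <- j
        next
      }
    }
    modes <- rbind(modes, y[i, ])
    labels[i] <- nrow(modes)
  }
  list(modes = sweep(modes, 2, scl, "*"), labels = labels, n_iter = iter)
}

#' Prune low-proportion clusters
#'
#' Clusters holding fewer than `min_prop` of the fibers get label 0
#' (unassigned); the retained proportions are renormalised over assigned
#' fibers. Pruning everything is an error.
#'
#' @param labels integer cluster labels from [mean_shift()].
#' @param min_prop proportion threshold (default 0.02).
#' @return list `labels` (pruned set to 0), `proportions` (named, summing
#'   to 1 over retained clusters).
#' @export
prune_clusters <- function(labels, min_prop = 0.02) {
  tab <- table(labels[labels > 0])
  prop <- as.numeric(tab) / sum(tab)
  names(prop) <- names(tab)
  small <- names(prop)[prop < min_prop]
  if (length(small) == length(prop)) stop("all clusters pruned; lower min_prop")
  labels[labels %in% as.integer(small)] <- 0L
  kept <- table(labels[labels > 0])
  prop_kept <- as.numeric(kept) / sum(kept)
  names(prop_kept) <- names(kept)
  list(labels = labels, proportions = prop_kept)
}

#' Name clusters by their dominant isoform
#'
#' Each retained cluster is named after the isoform with the highest
#' cluster-mean transformed intensity; when the top two means are within
#' `hybrid_margin` log units the cluster is a hybrid of both, and when all
#' three means fall below the `low_quantile` quantile of the pooled
#' transformed values it is tagged `low-MyHC`.
#'
#' @param points n x 3 transformed matrix used for clustering.
#' @param labels cluster labels (0 = pruned).
#' @param isoforms channel names, in column order.
#' @param hybrid_margin,low_quantile see [typing_config()].
#' @return named character vector: cluster id -> type name.
#' @export
assign_types <- function(points, labels,
                         isoforms = c("type1", "type2A", "type2X"),
                         hybrid_margin = 0.2, low_quantile = 0.1) {
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) == 0) stop("no retained clusters")
  lowcut <- stats::quantile(as.numeric(points), low_quantile, type = 7)
  out <- character(length(ids))
  for (i in seq_along(ids)) {
    mu <- colMeans(points[labels == ids[i], , drop = FALSE])
    if (all(mu < lowcut)) {
      out[i] <- "low-MyHC"
      next
    }
    o <- order(mu, decreasing = TRUE)
    if (mu[o[1]] - mu[o[2]] < hybrid_margin) {
      out[i] <- paste0("hybrid-", isoforms[o[1]], "/", isoforms[o[2]])
    } else {
      out[i] <- isoforms[o[1]]
    }
  }
  stats::setNames(out, ids)
}

#' Per-sample myofiber-type composition
#'
#' Proportions of assigned (label != 0) fibers per cluster within each
#' sample; rows sum to 1. A sample with no assigned fibers yields an NA row
#' with a warning.
#'
#' @param labels cluster labels per fiber (0 = pruned).
#' @param sample_of sample id per fiber.
#' @param type_names optional cluster -> name map from [assign_types()]
#'   used for column names.
#' @return matrix samples x clusters.
#' @export
composition <- function(labels, sample_of, type_names = NULL) {
  ids <- sort(unique(labels[labels > 0]))
  samples <- unique(sample_of)
  out <- matrix(NA_real_, length(samples), length(ids),
                dimnames = list(samples, as.character(ids)))
  for (s in samples) {
    sel <- sample_of == s & labels > 0
    if (!any(sel)) {
      warning("sample '", s, "' has no assigned fibers")
      next
    }
    tab <- table(factor(labels[sel], levels = ids))
    out[s, ] <- as.numeric(tab) / sum(tab)
  }
  if (!is.null(type_names)) {
    colnames(out) <- paste0(type_names[as.character(ids)], " (", ids, ")")
  }
  out
}

#' Full typing stage: scale, transform, cluster, prune, name, compose
#'
#' @param mfi n x 3 matrix of MyHC1 / MyHC2A / MyHC2X(2B) mean intensities.
#' @param sample_of sample id per fiber.
#' @param cfg a [typing_config()].
#' @return a `cluster_model` list: `points` (transformed), `modes`,
#'   `labels`, `proportions`, `type_names`, `composition`, `sample_of`,
#'   `cfg`. Retained cluster counts outside the biologically expected 3-8
#'   range trigger a warning, not an error.
#' @export
fiber_typing <- function(mfi, sample_of, cfg = typing_config()) {
  scaled <- scale_per_sample(mfi, sample_of)
  pts <- log_transform(scaled, cfg$zero_floor)
  ms <- mean_shift(pts, cfg)
  pr <- prune_clusters(ms$labels, cfg$min_cluster_prop)
  k <- length(pr$proportions)
  if (k < 3 || k > 8) {
    warning(k, " retained cluster(s): outside the biologically expected 3-8 range")
  }
  tn <- assign_types(pts, pr$labels,
                     hybrid_margin = cfg$hybrid_margin,
                     low_quantile = cfg$low_quantile)
  comp <- composition(pr$labels, sample_of, tn)
  structure(list(points = pts, modes = ms$modes, labels = pr$labels,
                 proportions = pr$proportions, type_names = tn,
                 composition = comp, sample_of = sample_of, cfg = cfg),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("cluster_model: %d fibers, %d retained cluster(s)\n",
              nrow(x$points), length(x$proportions)))
  for (id in names(x$proportions)) {
    cat(sprintf("  cluster %s (%s): %.1f%%\n", id, x$type_names[id],
                100 * x$proportions[id]))
  }
  invisible(x)
}
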