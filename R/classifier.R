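#' @title Trainable pixel classifier for myofiber boundaries
#' @description A random-forest pixel classifier in the spirit of
#'   interactive pixel-classification tools: multi-scale image features
#'   (Gaussian smoothing, Laplacian, gradient magnitude, difference of
#'   Gaussians, structure-tensor and Hessian eigenvalues) feed a decision
#'   forest trained on sparse 'boundary' / 'not boundary' annotations; the
#'   output is a per-pixel boundary probability map.
#' @name boundary_classifier
NULL

DEFAULT_SIGMAS <- c(0.7, 1.0, 1.6, 3.5, 5.0)

shift_mat <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  ri <- pmin(pmax(seq_len(h) + dr, 1), h)
  ci <- pmin(pmax(seq_len(w) + dc, 1), w)
  m[ri, ci, drop = FALSE]
}

deriv_x <- function(m) (shift_mat(m, 0, 1) - shift_mat(m, 0, -1)) / 2  # along columns
deriv_y <- function(m) (shift_mat(m, 1, 0) - shift_mat(m, -1, 0)) / 2  # along rows

eigen2x2 <- function(a, b, c) {
  # symmetric [[a, b], [b, c]]: eigenvalues analytically
  tr2 <- (a + c) / 2
  disc <- sqrt(pmax(((a - c) / 2)^2 + b^2, 0))
  list(hi = tr2 + disc, lo = tr2 - disc)
}

#' Multi-scale feature stack for pixel classification
#'
#' For each sigma: Gaussian smoothing, Laplacian of Gaussian, Gaussian
#' gradient magnitude, difference of Gaussians (sigma vs 1.6 sigma), the two
#' structure-tensor eigenvalues and the two Hessian eigenvalues — 8 planes
#' per sigma.
#'
#' @param raster numeric H x W matrix.
#' @param sigmas positive smoothing scales in pixels.
#' @return H x W x (8 * length(sigmas)) array with named planes.
#' @export
compute_features <- function(raster, sigmas = DEFAULT_SIGMAS) {
  stopifnot(is.matrix(raster))
  if (length(sigmas) == 0) stop("empty sigma list")
  if (any(sigmas <= 0)) stop("sigmas must be positive")
  h <- nrow(raster); w <- ncol(raster)
  planes <- list()
  for (s in sigmas) {
    g <- gaussian_blur(raster, s)
    gx <- deriv_x(g); gy <- deriv_y(g)
    gxx <- deriv_x(gx); gyy <- deriv_y(gy); gxy <- deriv_y(gx)
    st <- eigen2x2(gaussian_blur(gx * gx, s),
                   gaussian_blur(gx * gy, s),
                   gaussian_blur(gy * gy, s))
    he <- eigen2x2(gxx, gxy, gyy)
    nm <- sprintf("s%.2f", s)
    planes[[paste0(nm, "_gauss")]] <- g
    planes[[paste0(nm, "_log")]] <- gxx + gyy
    planes[[paste0(nm, "_gradmag")]] <- sqrt(gx^2 + gy^2)
    planes[[paste0(nm, "_dog")]] <- g - gaussian_blur(raster, 1.6 * s)
    planes[[paste0(nm, "_st_hi")]] <- st$hi
    planes[[paste0(nm, "_st_lo")]] <- st$lo
    planes[[paste0(nm, "_hess_hi")]] <- he$hi
    planes[[paste0(nm, "_hess_lo")]] <- he$lo
  }
  out <- array(unlist(planes, use.names = FALSE), dim = c(h, w, length(planes)))
  dimnames(out) <- list(NULL, NULL, names(planes))
  out
}

features_at <- function(feat, rows, cols) {
  nf <- dim(feat)[3]
  x <- matrix(0, length(rows), nf)
  for (k in seq_len(nf)) x[, k] <- feat[, , k][cbind(rows, cols)]
  colnames(x) <- dimnames(feat)[[3]]
  x
}

#' Train the boundary pixel classifier
#'
#' Fits a probability random forest (100 trees, depth <= 12) on the feature
#' vectors at the annotated pixels. Deterministic given `seed` (single
#' threaded).
#'
#' @param raster single-channel matrix (typically the masked laminin
#'   image), or a list of such matrices to train across several sections.
#' @param annotations data frame with `row`, `col`, `class` columns, classes
#'   `boundary` / `not_boundary` (a list parallel to `raster` when training
#'   on several images); both classes must be present, with at least 10
#'   pixels each overall.
#' @param sigmas feature scales, see [compute_features()].
#' @param num_trees,max_depth forest size and depth cap.
#' @param seed integer seed.
#' @return a `boundary_classifier` (model + feature config + training
#'   accuracy estimate).
#' @export
train_classifier <- function(raster, annotations, sigmas = DEFAULT_SIGMAS,
                             num_trees = 100, max_depth = 12, seed = 1L) {
  if (is.matrix(raster)) {
    raster <- list(raster)
    annotations <- list(annotations)
  }
  stopifnot(is.list(raster), is.list(annotations),
            length(raster) == length(annotations))
  all_classes <- unlist(lapply(annotations, `[[`, "class"))
  if (length(unique(all_classes)) < 2) stop("annotations must contain both classes")
  if (min(table(all_classes)) < 10) stop("need at least 10 annotations per class")
  xs <- mapply(function(r, a) {
    feat <- compute_features(r, sigmas)
    features_at(feat, a$row, a$col)
  }, raster, annotations, SIMPLIFY = FALSE)
  x <- do.call(rbind, xs)
  df <- as.data.frame(x)
  df$.class <- factor(all_classes, levels = c("boundary", "not_boundary"))
  fit <- ranger::ranger(dependent.variable.name = ".class", data = df,
                        num.trees = num_trees, max.depth = max_depth,
                        probability = TRUE, seed = seed, num.threads = 1)
  structure(list(model = fit, sigmas = sigmas, train_seed = as.integer(seed),
                 feature_names = colnames(x),
                 train_accuracy = 1 - fit$prediction.error),
            class = "boundary_classifier")
}

#' @export
print.boundary_classifier <- function(x, ...) {
  cat(sprintf("boundary_classifier: %d features (sigmas %s), OOB accuracy %.3f\n",
              length(x$feature_names), paste(x$sigmas, collapse = "/"),
              x$train_accuracy))
  invisible(x)
}

#' Predict the boundary-probability map for an image
#'
#' @param classifier a trained `boundary_classifier`.
#' @param raster single-channel matrix with the same feature configuration
#'   as at training time.
#' @return a [probability_map()] (boundary-class probability per pixel).
#' @export
predict_probability <- function(classifier, raster) {
  stopifnot(inherits(classifier, "boundary_classifier"), is.matrix(raster))
  feat <- compute_features(raster, classifier$sigmas)
  if (!identical(dimnames(feat)[[3]], classifier$feature_names)) {
    stop("feature configuration mismatch between training and prediction")
  }
  h <- nrow(raster); w <- ncol(raster)
  x <- as.data.frame(matrix(feat, h * w, dim(feat)[3]))
  names(x) <- classifier$feature_names
  pred <- stats::predict(classifier$model, data = x, num.threads = 1)
  p <- matrix(pred$predictions[, "boundary"], h, w)
  probability_map(p, source = "internal_classifier")
}
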