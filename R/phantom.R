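#' @title Synthetic tissue phantoms with per-fiber ground truth
#' @description Generates stained muscle cross-sections in silico: a
#'   Lloyd-relaxed Voronoi mosaic of fibers inside an elliptical tissue
#'   region, bright laminin on the inter-fiber boundaries, type-specific
#'   myosin heavy chain intensities (including hybrid fibers), pixel noise,
#'   and mask-worthy artifacts (dirt blobs, a fold, elongated
#'   longitudinally-cut fibers). Every fiber's identity, type, intensity and
#'   cross-sectional area is known, so downstream stages can be validated
#'   without real data.
#' @name phantom
NULL

#' Default per-type, per-channel intensity model
#'
#' Log-normal per-fiber mean intensities on the 16-bit scale. Each pure type
#' is bright (`bright`) in its own isoform channel and dim (`dim`) in the
#' others; hybrid fibers get the 0.5/0.5 convex mixture of the 2A and 2X
#' pure-type means. The laminin channel is uniformly dim inside fibers.
#'
#' @param bright,dim expected per-fiber mean intensity of expressed /
#'   non-expressed isoforms.
#' @param lamin_interior expected laminin intensity inside fibers.
#' @param sdlog_bright,sdlog_dim log-scale dispersion of the per-fiber means.
#' @return list with `mean` and `sdlog` matrices (type x channel).
#' @export
default_intensity_model <- function(bright = 2500, dim = 150, lamin_interior = 300,
                                    sdlog_bright = 0.25, sdlog_dim = 0.35) {
  types <- c("type1", "type2A", "type2X", "hybrid")
  chans <- c("MYHC1", "MYHC2A", "MYHC2X_OR_2B", "LAMININ")
  mean <- matrix(dim, 4, 4, dimnames = list(types, chans))
  mean["type1", "MYHC1"] <- bright
  mean["type2A", "MYHC2A"] <- bright
  mean["type2X", "MYHC2X_OR_2B"] <- bright
  # hybrid co-expresses 2A and 2X at half strength
  mean["hybrid", "MYHC2A"] <- (bright + dim) / 2
  mean["hybrid", "MYHC2X_OR_2B"] <- (bright + dim) / 2
  mean[, "LAMININ"] <- lamin_interior
  sdlog <- matrix(sdlog_dim, 4, 4, dimnames = dimnames(mean))
  sdlog[mean > 2 * dim] <- sdlog_bright
  list(mean = mean, sdlog = sdlog)
}

#' Specify a synthetic section phantom
#'
#' Defaults describe a realistic human section at 2.6 um/px: ~400 fibers of
#' mean cross-sectional area ~2800 um^2, a 3-pixel laminin boundary, modest
#' read noise and 25% shading.
#'
#' @param width,height image size in pixels.
#' @param pixel_size_um physical pixel size (um).
#' @param n_fibers number of fibers tessellating the tissue ellipse.
#' @param type_proportions named nonnegative proportions over
#'   `type1, type2A, type2X, hybrid`; must sum to 1.
#' @param intensity_model per type x channel intensity model, see
#'   [default_intensity_model()].
#' @param boundary_width_px laminin boundary width (px, >= 1).
#' @param boundary_intensity laminin intensity on boundaries (16-bit).
#' @param noise_sd Gaussian pixel noise standard deviation.
#' @param shading_amplitude amplitude of the multiplicative shading field in
#'   `[0, 1)` used by [degrade()].
#' @param artifact_spec list: `n_dirt`, `dirt_radius_px`, `n_folds`,
#'   `fold_size_px`, `n_elongated`, `elongated_aspect`.
#' @param seed integer seed; the phantom is deterministic given the spec.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(width = 512, height = 512, pixel_size_um = 2.6,
                         n_fibers = 400,
                         type_proportions = c(type1 = 0.45, type2A = 0.35,
                                              type2X = 0.15, hybrid = 0.05),
                         intensity_model = default_intensity_model(),
                         boundary_width_px = 3, boundary_intensity = 8000,
                         noise_sd = 80, shading_amplitude = 0.25,
                         artifact_spec = list(n_dirt = 3, dirt_radius_px = 5,
                                              n_folds = 1, fold_size_px = 40,
                                              n_elongated = 0, elongated_aspect = 4),
                         seed = 1L) {
  if (abs(sum(type_proportions) - 1) > 1e-9) stop("type_proportions must sum to 1")
  if (any(type_proportions < 0)) stop("type_proportions must be nonnegative")
  if (n_fibers < 1) stop("n_fibers must be >= 1")
  if (boundary_width_px < 1) stop("boundary_width_px must be >= 1")
  if (shading_amplitude < 0 || shading_amplitude >= 1) {
    stop("shading_amplitude must lie in [0, 1)")
  }
  tissue_area <- pi * (0.46 * width) * (0.46 * height)
  if (tissue_area / n_fibers < 9) stop("n_fibers too large: mean fiber area below 9 px^2")
  structure(list(width = width, height = height, pixel_size_um = pixel_size_um,
                 n_fibers = n_fibers, type_proportions = type_proportions,
                 intensity_model = intensity_model,
                 boundary_width_px = boundary_width_px,
                 boundary_intensity = boundary_intensity,
                 noise_sd = noise_sd, shading_amplitude = shading_amplitude,
                 artifact_spec = artifact_spec, seed = as.integer(seed)),
            class = "phantom_spec")
}

ellipse_mask <- function(h, w, frac = 0.46) {
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  ry <- frac * h; rx <- frac * w
  r <- matrix(seq_len(h), h, w)
  c <- matrix(seq_len(w), h, w, byrow = TRUE)
  ((r - cy) / ry)^2 + ((c - cx) / rx)^2 <= 1
}

# label map (full tessellation) -> logical inter-cell/periphery edge
label_edges <- function(lab) {
  h <- nrow(lab); w <- ncol(lab)
  e <- matrix(FALSE, h, w)
  dv <- lab[-h, ] != lab[-1, ]
  e[-h, ][dv] <- TRUE; e[-1, ][dv] <- TRUE
  dh <- lab[, -w] != lab[, -1]
  e[, -w][dh] <- TRUE; e[, -1][dh] <- TRUE
  e
}

voronoi_labels <- function(seed_img, mask) {
  flat <- EBImage::Image(matrix(0, nrow(seed_img), ncol(seed_img)))
  as_plain_matrix(EBImage::imageData(
    EBImage::propagate(flat, seed_img, mask = mask)))
}

draw_segment <- function(img, r0, c0, r1, c1, value) {
  n <- max(abs(r1 - r0), abs(c1 - c0), 1) + 1
  rr <- round(seq(r0, r1, length.out = n))
  cc <- round(seq(c0, c1, length.out = n))
  ok <- rr >= 1 & rr <= nrow(img) & cc >= 1 & cc <= ncol(img)
  img[cbind(rr[ok], cc[ok])] <- value
  img
}

#' Generate a synthetic stained section with ground truth
#'
#' Deterministic given `spec$seed`. Fibers are the cells of a Lloyd-relaxed
#' (2 iterations) Voronoi tessellation of random seeds inside an elliptical
#' tissue region; optional elongated fibers are grown from line-segment
#' seeds to emulate longitudinally cut fibers. Inter-fiber boundaries carry
#' bright laminin; fiber interiors carry per-fiber log-normal myosin heavy
#' chain intensities according to the type model, plus Gaussian pixel noise.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `image` ([section_image()], channels
#'   MyHC1/MyHC2A/MyHC2X/laminin), `labels` (truth [label_map()], boundaries
#'   carved out as 0), `mask` (truth [tissue_mask()]), `truth` (per-fiber
#'   data frame: `fiber_id`, centroid, `true_type`, per-channel true mean,
#'   `csa_um2`, `elongated_flag`) and `artifacts` (dirt centres, fold
#'   polygons).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  withr::with_seed(spec$seed, generate_phantom_impl(spec))
}

generate_phantom_impl <- function(spec) {
  h <- spec$height; w <- spec$width
  n <- spec$n_fibers
  tissue <- ellipse_mask(h, w)
  inside <- which(tissue)

  # seed points, then 2 Lloyd iterations for quasi-hexagonal cells
  pts_idx <- sample(inside, n)
  pr <- ((pts_idx - 1) %% h) + 1
  pc <- ((pts_idx - 1) %/% h) + 1
  for (it in 1:2) {
    seed_img <- matrix(0L, h, w)
    seed_img[cbind(pr, pc)] <- seq_len(n)
    lab <- voronoi_labels(seed_img, tissue)
    cr <- tapply(row(lab)[lab > 0], lab[lab > 0], mean)
    cc <- tapply(col(lab)[lab > 0], lab[lab > 0], mean)
    ids <- as.integer(names(cr))
    pr[ids] <- round(cr); pc[ids] <- round(cc)
    # keep seeds strictly inside tissue
    off <- which(!tissue[cbind(pr, pc)])
    if (length(off)) { # fall back to previous position by resampling
      repl <- sample(inside, length(off))
      pr[off] <- ((repl - 1) %% h) + 1
      pc[off] <- ((repl - 1) %/% h) + 1
    }
  }

  art <- spec$artifact_spec
  n_elong <- min(art$n_elongated %||% 0, n)
  mean_diam <- sqrt(sum(tissue) / n)
  seed_img <- matrix(0L, h, w)
  seed_img[cbind(pr, pc)] <- seq_len(n)
  elong_ids <- integer(0)
  if (n_elong > 0) {
    elong_ids <- sample(n, n_elong)
    half_len <- (art$elongated_aspect %||% 4) * mean_diam / 2
    for (id in elong_ids) {
      ang <- stats::runif(1, 0, pi)
      seed_img <- draw_segment(seed_img,
                               pr[id] - half_len * sin(ang), pc[id] - half_len * cos(ang),
                               pr[id] + half_len * sin(ang), pc[id] + half_len * cos(ang),
                               id)
    }
  }
  lab_full <- voronoi_labels(seed_img, tissue)

  # laminin boundary band between cells and at the tissue periphery
  band <- label_edges(lab_full) & tissue
  extra <- spec$boundary_width_px - 2L
  if (extra > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(ceiling(extra / 2)) + 1L, shape = "disc")
    band <- as_plain_matrix(EBImage::dilate(band * 1, brush)) > 0 & tissue
  }
  lab_truth <- lab_full
  lab_truth[band | !tissue] <- 0L

  # drop fibers whose interior vanished under the boundary band
  present <- sort(unique(lab_truth[lab_truth > 0]))
  remap <- integer(n); remap[present] <- seq_along(present)
  lab_truth[lab_truth > 0] <- remap[lab_truth[lab_truth > 0]]
  n_kept <- length(present)

  types <- names(spec$type_proportions)
  true_type <- sample(types, n_kept, replace = TRUE, prob = spec$type_proportions)
  model <- spec$intensity_model
  chans <- colnames(model$mean)
  mu <- model$mean[true_type, , drop = FALSE]
  sdl <- model$sdlog[true_type, , drop = FALSE]
  # per-fiber true mean intensity, E[.] = model mean
  true_mfi <- matrix(stats::rlnorm(n_kept * length(chans),
                                   meanlog = log(mu) - sdl^2 / 2, sdlog = sdl),
                     n_kept, length(chans), dimnames = list(NULL, chans))

  npx <- tabulate(lab_truth[lab_truth > 0], nbins = n_kept)
  cent_r <- tapply(row(lab_truth)[lab_truth > 0], lab_truth[lab_truth > 0], mean)
  cent_c <- tapply(col(lab_truth)[lab_truth > 0], lab_truth[lab_truth > 0], mean)

  background <- 30
  pix <- array(background, dim = c(h, w, 4))
  fg <- lab_truth > 0
  fid <- lab_truth[fg]
  for (k in seq_along(chans)) {
    ch <- matrix(background, h, w)
    ch[fg] <- true_mfi[fid, k]
    if (chans[k] == "LAMININ") ch[band] <- spec$boundary_intensity
    else ch[band] <- model$mean["type1", k]  # dim bleed on boundaries
    pix[, , k] <- ch
  }

  # artifacts: dirt blobs (bright laminin discs outside tissue) and folds
  dirt <- NULL
  n_dirt <- art$n_dirt %||% 0
  if (n_dirt > 0) {
    rad <- art$dirt_radius_px %||% 5
    # keep dirt clear of the tissue border so it forms its own small object
    d_out <- as_plain_matrix(EBImage::distmap((!tissue) * 1, metric = "euclidean"))
    outside <- which(!tissue & d_out > rad + 12 &
                       row(tissue) > rad & row(tissue) < h - rad &
                       col(tissue) > rad & col(tissue) < w - rad)
    if (length(outside) >= n_dirt) {
      di <- sample(outside, n_dirt)
      dr <- ((di - 1) %% h) + 1; dc <- ((di - 1) %/% h) + 1
      for (j in seq_len(n_dirt)) {
        rr <- pmax(1, dr[j] - rad):pmin(h, dr[j] + rad)
        cc <- pmax(1, dc[j] - rad):pmin(w, dc[j] + rad)
        blob <- outer(rr - dr[j], cc - dc[j], function(a, b) a^2 + b^2) <= rad^2
        lam <- pix[, , match("LAMININ", chans)]
        lam[rr, cc][blob] <- spec$boundary_intensity * 2
        pix[, , match("LAMININ", chans)] <- lam
      }
      dirt <- data.frame(row = dr, col = dc, radius_px = rad)
    }
  }
  folds <- list()
  n_folds <- art$n_folds %||% 0
  if (n_folds > 0) {
    sz <- art$fold_size_px %||% 40
    for (j in seq_len(n_folds)) {
      fi <- sample(inside, 1)
      fr <- ((fi - 1) %% h) + 1; fc <- ((fi - 1) %/% h) + 1
      # quadrilateral (x = col, y = row, 0-based vertex coordinates)
      poly <- cbind(x = fc + c(0, sz, sz * 0.8, -sz * 0.2) - 1,
                    y = fr + c(0, sz * 0.3, sz, sz * 0.6) - 1)
      poly[, "x"] <- pmin(pmax(poly[, "x"], 0), w)
      poly[, "y"] <- pmin(pmax(poly[, "y"], 0), h)
      cov <- polygon_pixels(poly, h, w)
      for (k in seq_along(chans)) {
        ch <- pix[, , k]
        ch[cov] <- pmin(ch[cov] * 2.5 + 2000, MAX_16BIT)
        pix[, , k] <- ch
      }
      folds[[j]] <- poly
    }
  }

  if (spec$noise_sd > 0) {
    pix <- pix + array(stats::rnorm(length(pix), 0, spec$noise_sd), dim = dim(pix))
  }
  pix <- round(pmin(pmax(pix, 0), MAX_16BIT))

  truth <- data.frame(fiber_id = seq_len(n_kept),
                      centroid_row = as.numeric(cent_r),
                      centroid_col = as.numeric(cent_c),
                      true_type = true_type,
                      csa_um2 = npx * spec$pixel_size_um^2,
                      elongated_flag = present %in% elong_ids)
  for (k in seq_along(chans)) truth[[paste0("mfi_", chans[k])]] <- true_mfi[, k]

  list(image = section_image(pix, spec$pixel_size_um,
                             c("MYHC1", "MYHC2A", "MYHC2X_OR_2B", "LAMININ"),
                             sample_id = paste0("phantom", spec$seed)),
       labels = label_map(lab_truth),
       mask = tissue_mask(tissue),
       truth = truth,
       artifacts = list(dirt = dirt, folds = folds))
}

#' Sample sparse training annotations from phantom truth
#'
#' Draws `n_per_class` pixel coordinates per class: 'boundary' pixels from
#' the inter-fiber band (background pixels adjacent to labelled fibers) and
#' 'not_boundary' pixels from fiber interiors. Classes are disjoint by
#' construction.
#'
#' @param truth_labels truth [label_map()] from [generate_phantom()].
#' @param n_per_class coordinates per class.
#' @param seed integer seed.
#' @return data frame with columns `row`, `col`, `class`.
#' @export
sample_annotations <- function(truth_labels, n_per_class, seed = 1L) {
  fg <- truth_labels > 0
  dil <- as_plain_matrix(EBImage::dilate(fg * 1, EBImage::makeBrush(5, "disc"))) > 0
  band_idx <- which(dil & !fg)
  interior_idx <- which(fg)
  if (n_per_class > length(band_idx) || n_per_class > length(interior_idx)) {
    stop("n_per_class exceeds available pixels")
  }
  withr::with_seed(seed, {
    b <- sample(band_idx, n_per_class)
    i <- sample(interior_idx, n_per_class)
  })
  h <- nrow(truth_labels)
  data.frame(row = (c(b, i) - 1) %% h + 1,
             col = (c(b, i) - 1) %/% h + 1,
             class = rep(c("boundary", "not_boundary"), each = n_per_class),
             stringsAsFactors = FALSE)
}

#' Analytic multiplicative shading field
#'
#' `1 + a * cos(2*pi*(r - 0.5)/H) * cos(2*pi*(c - 0.5)/W)`: a smooth
#' low-frequency field in `[1 - a, 1 + a]`, bright at the corners and dim in
#' the centre band, used both to degrade phantoms and as the oracle for the
#' shading-profile estimator.
#'
#' @param h,w field size in pixels.
#' @param amplitude `a` in `[0, 1)`.
#' @return numeric matrix.
#' @export
shading_field <- function(h, w, amplitude) {
  if (amplitude < 0 || amplitude >= 1) stop("amplitude must lie in [0, 1)")
  fr <- cos(2 * pi * (seq_len(h) - 0.5) / h)
  fc <- cos(2 * pi * (seq_len(w) - 0.5) / w)
  1 + amplitude * outer(fr, fc)
}

#' Degrade a section image with shading and noise
#'
#' Multiplies every channel by the analytic [shading_field()] and adds
#' clipped Gaussian noise; emulates an uncorrected slide-scanner acquisition.
#' The applied field is attached as attribute `"shading_field"` so tests can
#' use it as an oracle.
#'
#' @param image a [section_image()].
#' @param amplitude shading amplitude in `[0, 1)`; `>= 1` is an error.
#' @param noise_sd added Gaussian noise standard deviation.
#' @param seed integer seed for the noise.
#' @return degraded [section_image()] (16-bit clipped, rounded).
#' @export
degrade <- function(image, amplitude, noise_sd = 0, seed = 1L) {
  stopifnot(inherits(image, "section_image"))
  if (amplitude >= 1) stop("amplitude must be < 1 (>= 1 would null the signal)")
  if (amplitude < 0) stop("amplitude must be >= 0")
  d <- dim(image$pixels)
  field <- shading_field(d[1], d[2], amplitude)
  pix <- image$pixels * array(field, dim = d)
  if (noise_sd > 0) {
    pix <- pix + withr::with_seed(seed,
      array(stats::rnorm(length(pix), 0, noise_sd), dim = d))
  }
  pix <- round(pmin(pmax(pix, 0), MAX_16BIT))
  out <- section_image(pix, image$pixel_size_um, image$channel_roles,
                       image$sample_id, image$section_index)
  attr(out, "shading_field") <- field
  out
}
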