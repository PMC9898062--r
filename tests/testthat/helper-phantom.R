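# Shared phantom processing chain, built once and cached: generating the
# phantom, training the pixel classifier and predicting the probability map
# are the expensive steps, and many tests probe different aspects of the
# same chain.
.chain_cache <- new.env(parent = emptyenv())

phantom_chain <- function() {
  if (!is.null(.chain_cache$chain)) return(.chain_cache$chain)
  spec <- phantom_spec(width = 384, height = 384, n_fibers = 250, seed = 5,
                       artifact_spec = list(n_dirt = 2, dirt_radius_px = 5,
                                            n_folds = 0, n_elongated = 10,
                                            elongated_aspect = 4))
  ph <- generate_phantom(spec)
  mask <- auto_tissue_mask(ph$image)
  lam <- masked_laminin(ph$image, mask)
  ann <- sample_annotations(ph$labels, 300, seed = 2)
  clf <- train_classifier(lam, ann, seed = 7)
  prob <- predict_probability(clf, lam)
  seg <- filter_labels(segment_fibers(prob, mask), min_area_px = 9)
  img5 <- append_classification_channel(ph$image, prob)
  dm <- edge_distance_map(mask, ph$image$pixel_size_um)
  tab <- measure_section(img5, seg, dm)
  .chain_cache$chain <- list(spec = spec, ph = ph, mask = mask, lam = lam,
                             ann = ann, clf = clf, prob = prob, seg = seg,
                             img5 = img5, dm = dm, tab = tab)
  .chain_cache$chain
}

# Small synthetic MFI table: n ROIs x n_channels channels with given
# per-ROI values in chosen columns (everything else constant).
make_mfi <- function(n, n_channels = 5, mean5 = NULL, mean_boundary5 = NULL,
                     area = NULL, circ = NULL) {
  rows <- list()
  for (i in seq_len(n)) {
    for (ch in seq_len(n_channels)) {
      rows[[length(rows) + 1L]] <- data.frame(
        Label = sprintf("%04d:%d", i, ch),
        Area = if (is.null(area)) 1000 else area[i],
        Mean = if (ch == n_channels && !is.null(mean5)) mean5[i] else 100,
        StdDev = 1, Mode = 100, Min = 90, Max = 110, Median = 100,
        `Circ.` = if (is.null(circ)) 0.8 else circ[i],
        Mean_boundary = if (ch == n_channels && !is.null(mean_boundary5))
          mean_boundary5[i] else 200,
        StdDev_boundary = 5,
        Mean_distance = 50,
        check.names = FALSE)
    }
  }
  mfi_table(do.call(rbind, rows), n_channels)
}

# draw per-fiber MFI features from a generated phantom's truth table
truth_mfi <- function(ph) {
  as.matrix(ph$truth[, c("mfi_MYHC1", "mfi_MYHC2A", "mfi_MYHC2X_OR_2B")])
}
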