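test_that("per-sample RMS scaling is uncentered, unit-RMS, and sample-local", {
  set.seed(1)
  m <- matrix(stats::rlnorm(300, 6, 0.5), 100, 3)
  s <- rep(c("a", "b"), each = 50)
  out <- scale_per_sample(m, s)
  for (smp in c("a", "b")) {
    rms <- sqrt(colMeans(out[s == smp, ]^2))
    expect_equal(unname(rms), rep(1, 3), tolerance = 1e-9)
  }
  # constant column scales to exactly 1 (RMS of a constant is the constant)
  cm <- matrix(7, 20, 3)
  expect_true(all(scale_per_sample(cm, rep("x", 20)) == 1))
  # sample independence: perturbing b leaves a untouched
  m2 <- m; m2[s == "b", ] <- m2[s == "b", ] * 3
  expect_equal(scale_per_sample(m2, s)[s == "a", ], out[s == "a", ])
  # zero column errors with sample and channel named
  mz <- m; mz[s == "a", 2] <- 0
  expect_error(scale_per_sample(mz, s), "sample 'a', channel 2")
})

test_that("log transform maps 1 to 0, e to 1, and floors zeros finitely", {
  x <- matrix(c(1, exp(1), 0, 4), 2, 2)
  out <- log_transform(x, zero_floor = 1e-4)
  expect_equal(out[1, 1], 0)
  expect_equal(out[2, 1], 1)
  expect_equal(out[1, 2], log(1e-4))
  expect_true(all(is.finite(out)))
})

test_that("mean shift finds the modes of well-separated blobs", {
  # single point is its own mode
  one <- mean_shift(matrix(c(1, 2, 3), 1), typing_config(bandwidth_h = 0.1))
  expect_equal(one$labels, 1L)
  expect_equal(dim(one$modes), c(1L, 3L))
  # two tight blobs separated by 10h: every point labelled with its blob
  set.seed(7)
  h <- 0.3
  blob <- rbind(matrix(stats::rnorm(100, 0, h / 5), 50, 2),
                matrix(stats::rnorm(100, 10 * h, h / 5), 50, 2))
  cfg <- typing_config(bandwidth_h = h, scale_range = FALSE)
  ms <- mean_shift(blob, cfg)
  expect_equal(length(unique(ms$labels)), 2)
  expect_true(all(ms$labels[1:50] == ms$labels[1]))
  expect_true(all(ms$labels[51:100] == ms$labels[51]))
  expect_false(ms$labels[1] == ms$labels[51])
  # bandwidth at least the data diameter collapses everything to one mode
  big <- mean_shift(blob, typing_config(bandwidth_h = 10, scale_range = FALSE))
  expect_equal(length(unique(big$labels)), 1)
  expect_error(mean_shift(matrix(c(1, NA), 1)), "finite")
})

test_that("decreasing the bandwidth never decreases the pre-pruning mode count", {
  set.seed(12)
  x <- log_transform(matrix(stats::rlnorm(600, 0, 0.6), 200, 3), 1e-4)
  ks <- vapply(c(0.05, 0.04, 0.03, 0.02, 0.01), function(h) {
    nrow(mean_shift(x, typing_config(bandwidth_h = h))$modes)
  }, 0)
  expect_true(all(diff(ks) >= 0))
})

test_that("cluster pruning zeroes small clusters and renormalises", {
  labels <- c(rep(1L, 50), rep(2L, 49), rep(3L, 1))
  out <- prune_clusters(labels, min_prop = 0.02)
  expect_equal(sort(unique(out$labels)), c(0L, 1L, 2L))
  expect_equal(sum(out$proportions), 1)
  expect_equal(unname(out$proportions), c(50, 49) / 99)
  # nothing below the threshold -> unchanged
  same <- prune_clusters(c(rep(1L, 5), rep(2L, 5)), 0.02)
  expect_equal(same$labels, c(rep(1L, 5), rep(2L, 5)))
  expect_error(prune_clusters(rep(1:60, 1), min_prop = 0.5), "all clusters")
})

test_that("clusters are named by their dominant isoform with hybrid and low tags", {
  pts <- rbind(matrix(rep(c(0, -3, -3), each = 40), 40, 3),
               matrix(rep(c(-3, -0.05, 0.05), each = 40), 40, 3),
               matrix(rep(c(-6, -6, -6), each = 20), 20, 3))
  labels <- rep(1:3, c(40, 40, 20))
  nm <- assign_types(pts, labels, hybrid_margin = 0.2, low_quantile = 0.25)
  expect_equal(unname(nm["1"]), "type1")
  expect_equal(unname(nm["2"]), "hybrid-type2X/type2A")
  expect_equal(unname(nm["3"]), "low-MyHC")
})

test_that("per-sample composition rows sum to one and exclude pruned fibers", {
  labels <- c(1L, 1L, 2L, 0L, 2L, 2L)
  samples <- c("a", "a", "a", "b", "b", "b")
  comp <- composition(labels, samples)
  expect_equal(rowSums(comp), c(a = 1, b = 1), tolerance = 1e-9)
  expect_equal(unname(comp["a", ]), c(2 / 3, 1 / 3))
  expect_equal(unname(comp["b", ]), c(0, 1))   # the pruned fiber is excluded
  # all fibers in one cluster -> proportion 1
  comp1 <- composition(rep(1L, 4), rep("s", 4))
  expect_equal(unname(comp1[1, 1]), 1)
  expect_warning(composition(c(0L, 1L), c("x", "y")), "no assigned")
})

test_that("typing recovers a three-type phantom mixture", {
  spec <- phantom_spec(width = 620, height = 620, n_fibers = 1000, seed = 21,
                       type_proportions = c(type1 = 0.6, type2A = 0.3,
                                            type2X = 0.1, hybrid = 0))
  ph <- generate_phantom(spec)
  m <- truth_mfi(ph)
  found <- NULL
  for (h in c(0.03, 0.04, 0.05)) {
    cm <- suppressWarnings(fiber_typing(m, rep("s1", nrow(m)),
                                        typing_config(bandwidth_h = h)))
    if (length(cm$proportions) == 3) { found <- cm; break }
  }
  expect_false(is.null(found))
  ari <- mclust::adjustedRandIndex(found$labels, ph$truth$true_type)
  expect_gte(ari, 0.9)
  # composition recovered within 0.05 of the realised truth mixture (the
  # multinomial draw itself wanders ~1.5% around the nominal 0.6/0.3/0.1)
  realised <- sort(as.numeric(table(ph$truth$true_type)) / nrow(ph$truth),
                   decreasing = TRUE)
  expect_lt(max(abs(sort(found$proportions, decreasing = TRUE) - realised)), 0.05)
  expect_lt(max(abs(realised - c(0.6, 0.3, 0.1))), 0.05)
  # cluster names match the dominant isoforms
  expect_setequal(unname(found$type_names), c("type1", "type2A", "type2X"))
  expect_equal(unname(rowSums(found$composition)), 1, tolerance = 1e-9)
})
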