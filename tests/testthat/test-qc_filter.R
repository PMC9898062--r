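test_that("percentile bounds follow the type-7 linear interpolation formula", {
  v <- 1:100
  cuts <- percentile_bounds(v, 5, 95)
  # oracle: x_(k) + g * (x_(k+1) - x_(k)) with k = floor(1 + p(n-1))
  oracle <- function(p) {
    hpos <- 1 + p * 99
    k <- floor(hpos)
    v[k] + (hpos - k) * (v[k + 1] - v[k])
  }
  expect_equal(unname(cuts), c(oracle(0.05), oracle(0.95)))
  expect_equal(unname(cuts), c(5.95, 95.05))
  expect_equal(unname(percentile_bounds(v, 0, 100)), c(1, 100))
  expect_error(percentile_bounds(3, 5, 95), "at least 2")
})

test_that("default certainty filter removes exactly 5% per tail on distinct values", {
  tab <- make_mfi(1000, mean5 = sample(1:1000),
                  mean_boundary5 = rep(200, 1000))
  cfg <- filter_config(certainty_metrics = "Mean")
  f <- filter_certainty(tab, cfg)
  expect_equal(sum(f$pass_certainty), 900)
  # which ROIs pass: strictly between the 5th and 95th percentile cuts
  r5 <- as.data.frame(tab); r5 <- r5[r5$channel == 5, ]
  r5 <- r5[order(r5$roi_id), ]
  expect_setequal(f$roi_id[f$pass_certainty], r5$roi_id[r5$Mean %in% 51:950])
})

test_that("certainty filtering intersects the active metrics", {
  set.seed(2)
  m <- sample(1:1000); b <- sample(1:1000)
  tab <- make_mfi(1000, mean5 = m, mean_boundary5 = b)
  both <- filter_certainty(tab, filter_config())
  only_m <- filter_certainty(tab, filter_config(certainty_metrics = "Mean"))
  only_b <- filter_certainty(tab, filter_config(certainty_metrics = "Mean_boundary"))
  expect_equal(both$pass_certainty, only_m$pass_certainty & only_b$pass_certainty)
  # StdDev_boundary is inactive by default: its values never affect flags
  tab2 <- tab; tab2$StdDev_boundary <- rev(tab2$StdDev_boundary)
  tab2 <- mfi_table(as.data.frame(tab2), 5)
  expect_equal(filter_certainty(tab2, filter_config())$pass_certainty,
               both$pass_certainty)
})

test_that("CSA filter keeps 89% at the default 10/99 band and honours groups", {
  tab <- make_mfi(1000, area = sample(1:1000))
  f <- filter_csa(tab, filter_config())
  expect_equal(sum(f$pass_csa), 890)
  # two groups with disjoint CSA ranges get cuts inside their own ranges
  area <- c(1:500, 10001:10500)
  tab2 <- make_mfi(1000, area = area)
  grp <- rep(c("small", "large"), each = 500 * 5)[seq(1, 5000, by = 5)]
  r <- as.data.frame(tab2); r <- r[r$channel == 5, ]; r <- r[order(r$roi_id), ]
  grp <- ifelse(r$Area <= 500, "small", "large")
  f2 <- filter_csa(tab2, filter_config(), group_of = grp)
  # each group loses its own tails: 10% + 1% of 500 -> 55 and change
  expect_equal(sum(!f2$pass_csa[grp == "small"]), sum(!f2$pass_csa[grp == "large"]))
  expect_gt(sum(f2$pass_csa), 0)
  small_excl <- r$Area[grp == "small"][!f2$pass_csa[grp == "small"]]
  expect_true(all(small_excl <= 500))
  # a tiny group passes trivially with a warning
  expect_warning(filter_csa(tab2, filter_config(),
                            group_of = c("solo", grp[-1])), "fewer than 2")
})

test_that("ROIs failed by certainty still shift the CSA cuts", {
  # pooled cuts must include all ROIs, so removing them would change flags
  area <- c(seq(100, 1099), seq(5000, 5999))
  tab <- make_mfi(2000, area = area, mean5 = c(rep(1000, 1000), rep(10, 1000)))
  f_all <- filter_csa(tab, filter_config())
  sub <- mfi_table(as.data.frame(tab)[rep(area <= 1099, each = 5), ], 5)
  f_sub <- filter_csa(sub, filter_config())
  # cuts over the pooled set differ from cuts over a certainty-passing subset
  expect_false(identical(sum(f_all$pass_csa[area <= 1099]), sum(f_sub$pass_csa)))
})

test_that("circularity filter removes exactly the bottom 1% and all-ties pass", {
  tab <- make_mfi(1000, circ = sample(seq(0.001, 1, length.out = 1000)))
  f <- filter_circularity(tab, filter_config())
  expect_equal(sum(f$pass_circ), 990)
  ties <- make_mfi(50, circ = rep(0.8, 50))
  expect_true(all(filter_circularity(ties, filter_config())$pass_circ))
})

test_that("elongated phantom fibers predominantly fail the circularity filter", {
  ch <- phantom_chain()
  mm <- myotyper:::match_labels(ch$seg, ch$ph$labels)
  mm <- mm[mm$iou >= 0.5, ]
  flags <- qc_filter(ch$tab)
  elong_truth <- ch$ph$truth$fiber_id[ch$ph$truth$elongated_flag]
  elong_pred <- sprintf("%04d", mm$pred_id[mm$truth_id %in% elong_truth])
  df <- as.data.frame(ch$tab)
  circ <- df[df$channel == 1, c("roi_id", "Circ.")]
  # elongated fibers sit in the low tail of the circularity distribution
  expect_lt(stats::median(circ[["Circ."]][circ$roi_id %in% elong_pred]),
            stats::quantile(circ[["Circ."]], 0.1))
})

test_that("aggregate codes encode the filter cascade", {
  flags <- data.frame(pass_certainty = c(FALSE, TRUE, TRUE, TRUE, FALSE),
                      pass_csa = c(TRUE, FALSE, TRUE, TRUE, FALSE),
                      pass_circ = c(TRUE, TRUE, FALSE, TRUE, FALSE))
  out <- aggregate_codes(flags)
  expect_equal(out$aggregate_code, c(0, 0.4, 0.7, 1, 0))
  expect_error(aggregate_codes(flags[, 1:2]), "all three")
})

test_that("filters are order-independent because cuts are pooled", {
  ch <- phantom_chain()
  f1 <- qc_filter(ch$tab)
  # evaluate filters in a different order and merge
  g <- Reduce(function(a, b) merge(a, b, by = "roi_id"),
              list(filter_circularity(ch$tab), filter_csa(ch$tab),
                   filter_certainty(ch$tab)))
  g <- aggregate_codes(g)
  g <- g[match(f1$roi_id, g$roi_id), ]
  expect_equal(f1$aggregate_code, g$aggregate_code)
})

test_that("failure fraction of a two-sided band matches (p + 100 - q)/100 on tie-free data", {
  set.seed(4)
  for (band in list(c(5, 95), c(10, 99), c(2, 90))) {
    v <- sample(seq_len(5000))
    tab <- make_mfi(500, mean5 = sample(v, 500))
    cfg <- filter_config(certainty_pct = band, certainty_metrics = "Mean")
    f <- filter_certainty(tab, cfg)
    expected <- (band[1] + 100 - band[2]) / 100
    expect_lt(abs(mean(!f$pass_certainty) - expected), 1 / 500 + 1e-9)
  }
})

test_that("replicate selection takes the argmax and enforces the 100-fiber floor", {
  expect_equal(select_replicate(c(s1 = 120, s2 = 140, s3 = 90))$section, "s2")
  best <- select_replicate(c(s1 = 95, s2 = 80))
  expect_false(best$retained)
  expect_equal(best$section, "s1")
  ok <- select_replicate(c(s1 = 100, s2 = 99))
  expect_true(ok$retained)
  # tie -> lowest section index
  expect_equal(select_replicate(c(`2` = 150, `1` = 150))$section, "1")
  expect_error(select_replicate(integer(0)), "no sections")
})
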