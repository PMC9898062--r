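test_that("automatic mask recovers the phantom tissue ellipse", {
  ch <- phantom_chain()
  iou <- sum(ch$mask & ch$ph$mask) / sum(ch$mask | ch$ph$mask)
  expect_gte(iou, 0.9)
})

test_that("small dirt blobs outside the tissue are excluded from the mask", {
  ch <- phantom_chain()
  dirt <- ch$ph$artifacts$dirt
  expect_gt(nrow(dirt), 0)
  # blob area ~ pi * 5^2 < min_area 2000 px^2
  expect_true(all(!ch$mask[cbind(dirt$row, dirt$col)]))
})

test_that("blank images raise a no-tissue error", {
  img <- section_image(matrix(0, 32, 32), 1, "LAMININ")
  expect_error(auto_tissue_mask(img), "no tissue")
  img2 <- section_image(array(5, c(32, 32, 2)), 1, c("MYHC1", "MYHC2A"))
  expect_error(auto_tissue_mask(img2), "LAMININ")
})

test_that("polygon edits add, remove, and are idempotent / last-wins", {
  m <- tissue_mask(matrix(TRUE, 20, 20))
  sq <- cbind(x = c(5, 10, 10, 5), y = c(5, 5, 10, 10))
  removed <- apply_mask_edits(m, list(polygon_edit("remove", sq)))
  inside <- removed[7, 7]; expect_false(inside)
  expect_true(removed[3, 3])
  # add-then-remove the same polygon: pixels end 0
  both <- apply_mask_edits(m, list(polygon_edit("add", sq),
                                   polygon_edit("remove", sq)))
  expect_false(both[7, 7])
  # empty edit list leaves the mask unchanged
  same <- apply_mask_edits(m, list())
  expect_equal(as.vector(same), as.vector(m))
  expect_equal(attr(removed, "edits_applied"), 1L)
  # out-of-bounds vertices rejected
  expect_error(apply_mask_edits(m, list(polygon_edit("remove",
    cbind(x = c(-5, 10, 10), y = c(0, 0, 10))))), "bounds")
  expect_error(polygon_edit("add", cbind(x = c(1, 2), y = c(1, 2))), "3 vertices")
})

test_that("polygon rasterisation uses even-odd pixel-center coverage", {
  # unit-aligned square [2,6) x [3,8): covers pixel centers at x 2.5..5.5
  sq <- cbind(x = c(2, 6, 6, 2), y = c(3, 3, 8, 8))
  cov <- myotyper:::polygon_pixels(sq, 12, 12)
  expect_equal(sum(cov), 4 * 5)
  expect_true(cov[4, 3])           # row 4 center y=3.5, col 3 center x=2.5
  expect_false(cov[4, 7])          # x=6.5 outside half-open edge
})

test_that("removing a fold from the mask removes its ROIs downstream", {
  ch <- phantom_chain()
  poly <- cbind(x = c(100, 180, 180, 100), y = c(100, 100, 180, 180))
  edited <- apply_mask_edits(ch$mask, list(polygon_edit("remove", poly)))
  seg <- filter_labels(segment_fibers(ch$prob, edited), 9)
  cov <- myotyper:::polygon_pixels(poly, nrow(seg), ncol(seg))
  expect_true(all(seg[cov] == 0))
})

test_that("masked laminin honours its closed-form contract", {
  ch <- phantom_chain()
  lamch <- get_channel(ch$ph$image, "LAMININ")
  # mask of all ones returns the channel untouched
  all1 <- tissue_mask(matrix(TRUE, nrow(lamch), ncol(lamch)))
  expect_equal(masked_laminin(ch$ph$image, all1), lamch)
  # mask of all zeros returns a constant at the median
  all0 <- tissue_mask(matrix(FALSE, nrow(lamch), ncol(lamch)))
  out0 <- masked_laminin(ch$ph$image, all0)
  expect_true(all(out0 == round(stats::median(lamch))))
  # identity deep inside tissue, outside-median far outside (beyond 4 sigma)
  sigma <- 4
  d_in <- edge_distance_map(ch$mask, 1)
  deep <- d_in > 4 * sigma
  out <- masked_laminin(ch$ph$image, ch$mask, sigma)
  expect_true(all(abs(out[deep] - lamch[deep]) <= 1))
  d_out <- edge_distance_map(tissue_mask(!(ch$mask > 0)), 1)
  far_out <- d_out > 4 * sigma
  med <- stats::median(lamch[!ch$mask])
  expect_true(all(abs(out[far_out] - med) <= 1))
})

test_that("edge distance map matches the brute-force Euclidean oracle", {
  # single foreground pixel: distance 1 x pixel size
  m1 <- matrix(FALSE, 5, 5); m1[3, 3] <- TRUE
  d1 <- edge_distance_map(tissue_mask(m1), 2.6)
  expect_equal(d1[3, 3], 2.6)
  expect_equal(sum(d1 > 0), 1)
  # 21x21 solid square: center distance 11 px (frame counts as background)
  m2 <- matrix(TRUE, 21, 21)
  d2 <- edge_distance_map(tissue_mask(m2), 1)
  expect_equal(d2[11, 11], 11)
  # full brute-force comparison on a random blob
  set.seed(8)
  m3 <- matrix(FALSE, 15, 15)
  m3[4:12, 3:13] <- TRUE; m3[7, 7] <- FALSE
  d3 <- edge_distance_map(tissue_mask(m3), 1)
  bgr <- which(!m3); bg_r <- (bgr - 1) %% 15 + 1; bg_c <- (bgr - 1) %/% 15 + 1
  for (idx in which(m3)) {
    r <- (idx - 1) %% 15 + 1; c <- (idx - 1) %/% 15 + 1
    brute <- sqrt(min((bg_r - r)^2 + (bg_c - c)^2,
                      r^2, (16 - r)^2, c^2, (16 - c)^2))
    expect_equal(d3[r, c], brute)
  }
  expect_error(edge_distance_map(tissue_mask(matrix(FALSE, 3, 3)), 1), "empty")
})

test_that("edge distances do not increase toward the mask border", {
  d <- edge_distance_map(tissue_mask(matrix(TRUE, 21, 21)), 1)
  ray <- d[11, 11:21]                 # center to the right edge
  expect_true(all(diff(ray) < 0))
  expect_equal(as.numeric(ray), seq(11, 1))
})
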