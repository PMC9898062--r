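test_that("block-average downsampling matches the arithmetic-mean oracle", {
  # constant image stays constant
  img <- section_image(matrix(7, 4, 4), 0.65, "LAMININ")
  out <- downsample_by_averaging(img, 4)
  expect_equal(dim(out$pixels)[1:2], c(1L, 1L))
  expect_equal(out$pixels[1, 1, 1], 7)
  # mean of 0..15
  img2 <- section_image(matrix(0:15, 4, 4), 0.65, "LAMININ")
  out2 <- downsample_by_averaging(img2, 4)
  expect_equal(out2$pixels[1, 1, 1], mean(0:15))
  # pixel size scales: 0.65 um x 4 = 2.6 um
  expect_equal(out2$pixel_size_um, 2.6)
})

test_that("trailing partial blocks are averaged over available pixels", {
  m <- matrix(seq_len(5 * 6), 5, 6)
  img <- section_image(m / 10, 1, "LAMININ")
  out <- downsample_by_averaging(img, 2)
  expect_equal(dim(out$pixels)[1:2], c(3L, 3L))
  expect_equal(out$pixels[3, 1, 1], mean(m[5, 1:2] / 10))  # 1-row block
  expect_equal(out$pixels[1, 1, 1], mean(m[1:2, 1:2] / 10))
})

test_that("downsampling warns when leaving the 1-5 um working range", {
  img <- section_image(matrix(1, 8, 8), 2.6, "LAMININ")
  expect_warning(downsample_by_averaging(img, 4), "working range")
  expect_error(downsample_by_averaging(img, 0), "positive")
})

test_that("shading profile of a flat image is identically 1", {
  img <- section_image(matrix(500, 64, 64), 1, "LAMININ")
  p <- estimate_shading_profile(img, 1)
  expect_equal(max(abs(p - 1)), 0, tolerance = 1e-6)
  expect_equal(mean(p), 1, tolerance = 1e-6)
  expect_error(estimate_shading_profile(section_image(matrix(0, 8, 8), 1, "LAMININ"), 1),
               "all-zero")
})

test_that("estimated profile recovers a known cosine shading field", {
  field <- shading_field(96, 96, 0.3)
  img <- section_image(round(4000 * field), 1, "LAMININ")
  p <- estimate_shading_profile(img, 1)
  expect_gt(stats::cor(as.vector(p), as.vector(field)), 0.95)
  expect_equal(mean(p), 1, tolerance = 1e-6)
})

test_that("median profile is the per-pixel median, renormalised", {
  profs <- lapply(c(0.1, 0.25, 0.4), function(a) {
    v <- shading_field(16, 16, a)
    shading_profile(v / mean(v), 1L)
  })
  med <- median_shading_profile(profs)
  oracle <- apply(array(unlist(profs), dim = c(16, 16, 3)), c(1, 2), stats::median)
  oracle <- oracle / mean(oracle)
  expect_equal(as.vector(med), as.vector(oracle), tolerance = 1e-12)
  # single profile -> itself; identical profiles -> same profile
  one <- median_shading_profile(profs[1])
  expect_equal(as.vector(one), as.vector(profs[[1]] / mean(profs[[1]])), tolerance = 1e-12)
  expect_error(median_shading_profile(list(profs[[1]], shading_profile(matrix(1, 4, 4)))),
               "mismatched")
})

test_that("per-pixel median oracle: values {1, 2, 9} give 2 before renormalisation", {
  mk <- function(v) shading_profile(matrix(v, 2, 2), 1L)
  stack <- array(c(rep(1, 4), rep(2, 4), rep(9, 4)), dim = c(2, 2, 3))
  med_raw <- apply(stack, c(1, 2), stats::median)
  expect_true(all(med_raw == 2))
  med <- median_shading_profile(list(mk(1), mk(2), mk(9)))
  expect_true(all(abs(med - 1) < 1e-12))  # constant, so mean-1 renormalised
})

test_that("shading correction divides out the field", {
  truth <- matrix(3000, 80, 80)
  field <- shading_field(80, 80, 0.4)
  img <- section_image(truth * field, 1, "LAMININ")
  corrected <- apply_shading_correction(img, list(shading_profile(field, 1L)))
  expect_lte(max(abs(corrected$pixels[, , 1] - truth)), 1)
  expect_true(all(corrected$pixels >= 0))
  # identity profile changes nothing
  same <- apply_shading_correction(img, list(shading_profile(matrix(1, 80, 80), 1L)))
  expect_equal(same$pixels, round(img$pixels))
  expect_error(apply_shading_correction(
    section_image(array(1, c(8, 8, 2)), 1, c("MYHC1", "LAMININ")),
    list(shading_profile(matrix(1, 8, 8), 1L))), "missing shading profile")
})

test_that("estimated median profile halves the shading CV of degraded phantoms", {
  # the phantom truth isolates the shading component: tile means of the
  # degraded (resp. corrected) image relative to the clean image measure
  # the multiplicative field before and after correction
  chain <- phantom_chain()
  ph <- chain$ph
  deg <- degrade(ph$image, amplitude = 0.3, noise_sd = 20, seed = 3)
  ch <- channel_index(ph$image, "LAMININ")
  profs <- lapply(seq_len(n_channels(deg)), function(k)
    median_shading_profile(list(estimate_shading_profile(deg, k))))
  corr <- apply_shading_correction(deg, profs)
  clean <- pmax(ph$image$pixels[, , ch], 1)
  shading_cv <- function(m) {
    tn <- myotyper:::block_mean(m, 48)
    td <- myotyper:::block_mean(clean, 48)
    frac <- myotyper:::block_mean((ph$mask > 0) * 1, 48)
    r <- (tn / td)[frac > 0.99]          # tiles fully inside tissue
    stats::sd(r) / mean(r)
  }
  cv_deg <- shading_cv(deg$pixels[, , ch])
  cv_corr <- shading_cv(corr$pixels[, , ch])
  expect_lt(cv_corr, 0.5 * cv_deg)
})
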