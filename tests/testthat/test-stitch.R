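test_that("stitching conserves constant scores and covers every pixel", {
  # biases give per-channel constant sigmoid scores; argmax must pick the
  # largest, with ties resolved to the lowest class code
  biases <- c(-1, 0.5, 2, 0.5, -2)
  model <- constant_model(biases, base_channels = 2L, patch_size = 128L)
  img <- array(128L, c(320, 288, 3))
  pred <- predict_roi(model, img, stitch_spec(128, 64))
  want <- 1 / (1 + exp(-biases))
  for (k in 1:5) {
    expect_equal(range(pred$scores[, , k]), rep(want[k], 2), tolerance = 1e-12)
  }
  expect_true(all(pred$labels == 2L))
  expect_true(all(pred$weight > 0))
})

test_that("argmax ties resolve to the lowest class code", {
  model <- constant_model(c(1, 1, 1, 1, 1), base_channels = 2L,
                          patch_size = 64L)
  pred <- predict_roi(model, array(100L, c(64, 64, 3)), stitch_spec(64, 64))
  expect_true(all(pred$labels == 0L))
})

test_that("clamped anchors reach the ROI border and interiors get 4 covers", {
  P <- 128L; s <- 64L
  pos <- rpcseg:::infer_positions(320L, P, s)
  expect_equal(pos[length(pos)] + P, 320L)
  # brute-force coverage count over a 1-D axis
  cover <- integer(320)
  for (p in pos) cover[(p + 1):(p + P)] <- cover[(p + 1):(p + P)] + 1L
  expect_true(all(cover >= 1L))
  expect_true(all(cover[(P + 1):(320 - P)] >= 2L))
  # odd extent: final anchor clamps rather than truncates
  pos2 <- rpcseg:::infer_positions(300L, P, s)
  expect_equal(pos2[length(pos2)], 300L - P)
})

test_that("with stride = patch size stitching degenerates to tiling", {
  set.seed(20)
  nb <- 2L; K <- 5L
  params <- rpcseg:::unet_init(nb, K, seed = 21)
  model <- constant_model(rep(0, K), base_channels = nb, patch_size = 64L)
  model$params <- params
  img <- array(sample(0:255, 128 * 128 * 3, TRUE), c(128, 128, 3))
  pred <- predict_roi(model, img, stitch_spec(64, 64))
  for (oy in c(0L, 64L)) {
    for (ox in c(0L, 64L)) {
      tile <- img[(oy + 1):(oy + 64), (ox + 1):(ox + 64), , drop = FALSE]
      direct <- rpcseg:::unet_scores(params, tile, nb, K)
      expect_equal(pred$scores[(oy + 1):(oy + 64), (ox + 1):(ox + 64), ],
                   direct, tolerance = 1e-12)
    }
  }
})

test_that("small ROIs are reflect-padded for inference only", {
  model <- constant_model(c(0, 0, 3, 0, 0), base_channels = 2L,
                          patch_size = 64L)
  pred <- predict_roi(model, array(100L, c(40, 52, 3)), stitch_spec(64, 64))
  expect_equal(dim(pred$labels), c(40L, 52L))
  expect_true(all(pred$labels == 2L))
})

test_that("the RGB palette renders and inverts exactly", {
  mask <- matrix(0L, 16, 16)
  expect_true(all(render_rgb(mask) == 0L))
  mask[4, 5] <- 2L
  rgb <- render_rgb(mask)
  expect_equal(sum(rgb[, , 1] == 230L), 1L)
  expect_equal(rgb[4, 5, ], c(230L, 0L, 0L))
  full <- matrix(c(0:4, 255L), 2, 3)
  expect_identical(rgb_to_codes(render_rgb(full)), full)
  expect_error(rgb_to_codes(array(7L, c(2, 2, 3))), "outside the palette")
})

test_that("class pixel counts are exact and conserve the image area", {
  set.seed(23)
  mask <- matrix(sample(c(0:4, 255L), 900, TRUE), 30, 30)
  mask[mask == 2L] <- 0L
  mask[sample(900, 123)] <- 2L
  counts <- count_class_pixels(mask)
  expect_equal(counts[["cancer"]], 123L)
  expect_equal(attr(counts, "rpc"), 123L)
  expect_equal(sum(counts), 900L)
})

test_that("ground-truth RPC counts track the generator's realized mixture", {
  set.seed(24)
  counts <- frac <- numeric(30)
  prof <- default_scanner_profiles()$philips
  for (i in 1:30) {
    mix <- c(normal_ducts = 0.05, cancer = runif(1, 0.05, 0.30),
             other_epithelium = 0.05, fat = 0.05)
    spec <- cohort_spec(roi_size = 96, class_mixture = mix, seed = i)
    roi <- generate_roi(spec, prof, seed = 700 + i)
    counts[i] <- count_class_pixels(roi$mask)[["cancer"]]
    frac[i] <- attr(roi, "fractions")[["cancer"]]
  }
  expect_gt(stats::cor(counts, frac, method = "spearman"), 0.9)
  expect_equal(counts, frac * 96^2)  # bookkeeping is exact
})
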