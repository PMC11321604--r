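test_that("one-hot targets and ignore weighting behave as specified", {
  m <- matrix(0L, 8, 8)
  tw <- make_targets(m)
  expect_true(all(tw$target[, , 1] == 1))
  expect_true(all(tw$target[, , 2:5] == 0))
  expect_true(all(tw$weight == 1))

  m[3, 4] <- rpc_ignore_code()
  tw <- make_targets(m)
  expect_equal(sum(tw$weight == 0), 1L)
  expect_equal(tw$weight[3, 4], 0)

  set.seed(2)
  m <- matrix(sample(c(0:4, 255L), 64, TRUE), 8, 8)
  tw <- make_targets(m)
  sums <- apply(tw$target, c(1, 2), sum)
  expect_true(all(sums[m != 255L] == 1))
  expect_error(make_targets(matrix(9L, 2, 2)), "9")
})

test_that("the compiled BCE loss equals an independent scalar recomputation", {
  set.seed(3)
  nb <- 3L; K <- 5L
  params <- rpcseg:::unet_init(nb, K, seed = 4)
  img <- array(runif(4 * 4 * 3, -0.5, 0.5), c(4, 4, 3))
  mask <- matrix(sample(c(0:4, 255L), 16, TRUE), 4, 4)
  tw <- make_targets(mask)
  got <- rpcseg:::cpp_unet_loss_grad(params, img, tw$target, tw$weight,
                                     nb, K)$loss
  scores <- rpcseg:::cpp_unet_forward(params, img, nb, K)
  want <- rpcseg:::bce_reference(scores, tw$target, tw$weight)
  expect_equal(got, want, tolerance = 1e-8)
})

test_that("analytic gradients match finite differences", {
  set.seed(5)
  nb <- 2L; K <- 5L
  params <- rpcseg:::unet_init(nb, K, seed = 6)
  img <- array(runif(8 * 8 * 3, -0.5, 0.5), c(8, 8, 3))
  mask <- matrix(sample(c(0:4, 255L), 64, TRUE), 8, 8)
  tw <- make_targets(mask)
  lg <- rpcseg:::cpp_unet_loss_grad(params, img, tw$target, tw$weight, nb, K)
  idx <- sample(length(params), 10)
  for (i in idx) {
    e <- 1e-5
    up <- params; up[i] <- up[i] + e
    dn <- params; dn[i] <- dn[i] - e
    num <- (rpcseg:::cpp_unet_loss_grad(up, img, tw$target, tw$weight,
                                        nb, K)$loss -
            rpcseg:::cpp_unet_loss_grad(dn, img, tw$target, tw$weight,
                                        nb, K)$loss) / (2 * e)
    expect_equal(lg$grad[i], num, tolerance = 1e-4)
  }
})

test_that("the early-stopping rule traces hand-computed sequences", {
  tr <- rpcseg:::early_stop_trace(c(1.0, 0.9, 0.95, 0.93), patience = 2)
  expect_equal(tr$stopped_at, 4L)
  expect_equal(tr$best_epoch, 2L)
  tr2 <- rpcseg:::early_stop_trace(c(0.5), patience = 3)
  expect_equal(tr2$stopped_at, 1L)
  expect_equal(tr2$best_epoch, 1L)
  tr3 <- rpcseg:::early_stop_trace(c(1, 0.9, 0.8, 0.7), patience = 2)
  expect_equal(tr3$best_epoch, 4L)
})

test_that("training is seeded-deterministic, capped by max_epochs, and validated", {
  rois <- tiny_cohort()
  ps <- build_patchset(rois, patch_spec(48, 48), seed = 1)
  cfg <- train_config(base_channels = 3L, lr = 2e-3, max_epochs = 1L,
                      patience = 0.5, batch_size = 4L, val_fraction = 0.34,
                      seed = 2, normalize = FALSE, augment = TRUE)
  m1 <- train(ps, rois, cfg)
  expect_equal(nrow(m1$history), 1L)  # max_epochs 1 -> exactly one epoch
  m2 <- train(ps, rois, cfg)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
  expect_equal(m1$best_epoch, which.min(m1$history$val_loss))

  single <- ps[ps$case_id == ps$case_id[1], , drop = FALSE]
  attr(single, "patch_size") <- 48L
  expect_error(train(single, rois, cfg), "validation cases")
})

test_that("model checkpoints round-trip through JSON", {
  rois <- tiny_cohort()
  ps <- build_patchset(rois, patch_spec(48, 48), seed = 1)
  cfg <- train_config(base_channels = 3L, lr = 2e-3, max_epochs = 1L,
                      patience = 0.5, batch_size = 4L, val_fraction = 0.34,
                      seed = 2, normalize = FALSE, augment = FALSE)
  m <- train(ps, rois, cfg)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  back <- load_model(path)
  expect_equal(back$params, m$params)
  expect_equal(back$patch_size, m$patch_size)
  pred1 <- predict_roi(m, rois[[1]])
  pred2 <- predict_roi(back, rois[[1]])
  expect_identical(pred1$labels, pred2$labels)
})
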