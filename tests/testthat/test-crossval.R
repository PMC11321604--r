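make_manifest <- function(rois) {
  do.call(rbind, lapply(rois, function(r) {
    data.frame(case_id = r$case_id, center_id = r$center_id,
               scanner_type = r$scanner_type,
               image_path = paste0(r$case_id, "_i.png"),
               mask_path = paste0(r$case_id, "_m.png"),
               stringsAsFactors = FALSE)
  }))
}

test_that("fold construction partitions cases by scanner without leakage", {
  rois <- tiny_cohort()
  manifest <- make_manifest(rois)
  plan <- crossval_plan(manifest)
  expect_equal(length(plan$folds), 2L)
  all_cases <- unique(manifest$case_id)
  for (f in plan$folds) {
    expect_length(intersect(f$train_cases, f$test_cases), 0L)
    expect_setequal(c(f$train_cases, f$test_cases), all_cases)
  }
  one <- manifest[manifest$scanner_type == "philips", ]
  expect_error(crossval_plan(one), ">= 2 scanner types")
})

test_that("cross-validation trains per fold, scores held-out scanners, and pools", {
  rois <- tiny_cohort()
  manifest <- make_manifest(rois)
  plan <- crossval_plan(manifest, normalize = TRUE, augment = FALSE)
  cfg <- train_config(base_channels = 4L, lr = 5e-3, max_epochs = 3L,
                      patience = 1L, batch_size = 4L, val_fraction = 0.34,
                      seed = 3, normalize = TRUE, augment = FALSE)
  cv <- run_crossval(rois, plan, patch_spec(48, 24), cfg)
  expect_length(cv$summaries, 2L)
  expect_s3_class(cv$final_model, "trained_model")
  expect_setequal(vapply(cv$summaries, function(s) s$scanner_type,
                         character(1)), c("philips", "3dhistech"))
  # every test case was scored exactly once, on its own scanner
  expect_equal(length(cv$scores), length(rois))
  tab <- crossval_table(cv)
  expect_equal(tab$n, c(3L, 3L))
  expect_true(all(tab$mean_f1 >= 0 & tab$mean_f1 <= 1))
  # pooling contract: fold means are pooled iff every fold has a positive SE
  ses <- vapply(cv$summaries, function(s) stats::sd(s$case_f1) / sqrt(s$n),
                numeric(1))
  if (all(ses > 0)) {
    expect_s3_class(cv$meta, "meta_result")
    expect_equal(cv$meta$k, 2L)
  } else {
    expect_null(cv$meta)
  }
})

test_that("folds over identical scanner hardware perform alike", {
  # two "scanners" share the philips color profile, so the two folds are
  # exchangeable up to sampling noise: their mean F1s must sit close
  spec <- cohort_spec(n_cases = 6, roi_size = 128, seed = 60)
  pseudo <- default_scanner_profiles()$philips
  rois <- list(); i <- 0
  for (name in c("philips", "hamamatsu")) {
    prof <- pseudo; prof$name <- name
    for (k in 1:6) {
      i <- i + 1
      rois[[i]] <- generate_roi(spec, prof, seed = 800 + i,
                                case_id = sprintf("%s_c%d", name, k),
                                center_id = name)
    }
  }
  plan <- crossval_plan(make_manifest(rois), normalize = FALSE,
                        augment = FALSE)
  cfg <- train_config(base_channels = 6L, lr = 5e-3, max_epochs = 24L,
                      patience = 6L, batch_size = 4L, val_fraction = 0.25,
                      seed = 4, normalize = FALSE, augment = FALSE)
  cv <- run_crossval(rois, plan, patch_spec(64, 32), cfg,
                     final_model = FALSE)
  expect_null(cv$final_model)
  means <- vapply(cv$summaries, function(s) s$mean_f1, numeric(1))
  expect_lt(abs(means[1] - means[2]), 0.1)
  expect_true(all(means > 0.8))
  expect_s3_class(cv$meta, "meta_result")
})
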