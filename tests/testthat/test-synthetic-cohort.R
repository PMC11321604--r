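test_that("ROI generation is seed-deterministic and mask is scanner-invariant", {
  spec <- cohort_spec(roi_size = 96, seed = 1)
  pr <- default_scanner_profiles()
  a <- generate_roi(spec, pr$philips, seed = 5)
  b <- generate_roi(spec, pr$philips, seed = 5)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  c <- generate_roi(spec, pr$`3dhistech`, seed = 5)
  expect_identical(a$mask, c$mask)
  expect_false(identical(a$image, c$image))
})

test_that("an all-zero class mixture yields a pure-stroma background mask", {
  spec <- cohort_spec(roi_size = 64,
                      class_mixture = c(normal_ducts = 0, cancer = 0,
                                        other_epithelium = 0, fat = 0),
                      seed = 2)
  roi <- generate_roi(spec, default_scanner_profiles()$philips, seed = 3)
  expect_true(all(roi$mask == 0L))
})

test_that("infeasible mixtures are rejected", {
  expect_error(cohort_spec(class_mixture = c(normal_ducts = 0.4, cancer = 0.4,
                                             other_epithelium = 0.2,
                                             fat = 0.2)),
               "sum to <= 1")
  expect_error(cohort_spec(class_mixture = c(normal_ducts = -0.1, cancer = 0.2,
                                             other_epithelium = 0, fat = 0)))
})

test_that("realized cancer fraction tracks the requested mixture", {
  # Monte-Carlo check of the placement algorithm at the training scale
  spec <- cohort_spec(roi_size = 512,
                      class_mixture = c(normal_ducts = 0.05, cancer = 0.20,
                                        other_epithelium = 0.05, fat = 0.05),
                      seed = 9)
  fr <- vapply(1:50, function(s) {
    geom <- rpcseg:::with_seed(1000 + s, rpcseg:::generate_geometry(spec))
    geom$fractions[["cancer"]]
  }, numeric(1))
  expect_lt(abs(mean(fr) - 0.20), 0.05)
})

test_that("fat is brighter than cancer in every generated ROI", {
  spec <- cohort_spec(roi_size = 96, seed = 4)
  pr <- default_scanner_profiles()
  for (s in 1:5) {
    for (p in pr) {
      roi <- generate_roi(spec, p, seed = 200 + s)
      lum <- (roi$image[, , 1] + roi$image[, , 2] + roi$image[, , 3]) / 3
      if (any(roi$mask == 4L) && any(roi$mask == 2L)) {
        expect_gt(mean(lum[roi$mask == 4L]), mean(lum[roi$mask == 2L]))
      }
    }
  }
})

test_that("scanner profiles shift the rendered colors detectably", {
  spec <- cohort_spec(roi_size = 96, seed = 6)
  pr <- default_scanner_profiles()
  a <- generate_roi(spec, pr$philips, seed = 7)
  b <- generate_roi(spec, pr$`3dhistech`, seed = 7)
  expect_gt(max(abs(apply(a$image, 3, mean) - apply(b$image, 3, mean))), 2)
})

test_that("generate_cohort writes a consistent manifest and files", {
  spec <- cohort_spec(n_cases = 3, roi_size = 64, seed = 11)
  d <- withr::local_tempdir()
  manifest <- generate_cohort(spec, default_scanner_profiles(), d)
  expect_equal(nrow(manifest), 12L)
  expect_equal(length(unique(manifest$case_id)), 12L)
  expect_equal(unname(table(manifest$scanner_type)[rpc_scanner_types()]),
               rep(3L, 4), ignore_attr = TRUE)
  expect_true(all(file.exists(file.path(d, manifest$image_path))))
  rois <- load_cohort(read_manifest(file.path(d, "manifest.csv")), d)
  expect_s3_class(rois[[1]], "annotated_roi")
  # same seed regenerates byte-identical outputs
  d2 <- withr::local_tempdir()
  generate_cohort(spec, default_scanner_profiles(), d2)
  expect_identical(readLines(file.path(d, "manifest.csv")),
                   readLines(file.path(d2, "manifest.csv")))
  f <- manifest$image_path[1]
  expect_identical(readBin(file.path(d, f), "raw", 1e6),
                   readBin(file.path(d2, f), "raw", 1e6))
})
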