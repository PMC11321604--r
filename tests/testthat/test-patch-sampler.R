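test_that("anchor enumeration matches the closed form and handles edges", {
  spec <- patch_spec(512, 256)
  a <- enumerate_anchors(c(1024, 1024), spec)
  expect_equal(nrow(a), 9L)
  expect_equal(a$x[1:3], c(0L, 256L, 512L))  # row-major order
  expect_equal(nrow(enumerate_anchors(c(512, 512), spec)), 1L)
  expect_warning(none <- enumerate_anchors(c(511, 512), spec), "smaller")
  expect_equal(nrow(none), 0L)
})

test_that("anchor count equals the closed form on random shapes", {
  set.seed(31)
  for (i in 1:50) {
    p <- sample(8:64, 1)
    s <- sample(seq_len(p), 1)
    h <- sample(p:(4 * p), 1); w <- sample(p:(4 * p), 1)
    a <- enumerate_anchors(c(h, w), patch_spec(p, s))
    closed <- (floor((h - p) / s) + 1) * (floor((w - p) / s) + 1)
    expect_equal(nrow(a), closed)
    # brute-force: every anchor in-bounds and on the stride grid
    expect_true(all(a$x %% s == 0 & a$x + p <= w))
    expect_true(all(a$y %% s == 0 & a$y + p <= h))
  }
})

test_that("the 10% inclusion threshold is inclusive and foreground-only", {
  p <- 120L  # area 14400, 10% = 1440 exactly
  spec <- patch_spec(p, p, inclusion_fraction = 0.10)
  anchors <- data.frame(x = 0L, y = 0L)
  mk <- function(n_cancer, filler = 0L) {
    m <- matrix(filler, p, p)
    if (n_cancer > 0) m[seq_len(n_cancer)] <- 2L
    m
  }
  expect_equal(nrow(filter_by_content(anchors, mk(1440L), spec)), 1L)
  expect_equal(nrow(filter_by_content(anchors, mk(1439L), spec)), 0L)
  # all-stroma (background) patch is dropped
  expect_equal(nrow(filter_by_content(anchors, mk(0L), spec)), 0L)
  # ignore pixels never qualify a patch
  expect_equal(nrow(filter_by_content(anchors, mk(0L, rpc_ignore_code()),
                                      spec)), 0L)
  # qualifying classes are all tagged
  m <- matrix(0L, p, p); m[1:2000] <- 2L; m[2001:4000] <- 4L
  got <- filter_by_content(anchors, m, spec)
  expect_equal(got$classes, "2,4")
})

test_that("the per-case class cap subsamples uniformly and reproducibly", {
  patches <- data.frame(case_id = "c1", roi_id = 1L, x = seq_len(70) * 8L,
                        y = 0L, classes = "2", stringsAsFactors = FALSE)
  spec <- patch_spec(64, 64, per_case_class_cap = 50L)
  capped <- apply_cap(patches, spec, seed = 3)
  expect_equal(nrow(capped), 50L)
  expect_identical(as.data.frame(apply_cap(patches, spec, seed = 3)),
                   as.data.frame(capped))
  expect_false(identical(as.data.frame(apply_cap(patches, spec, seed = 4)),
                         as.data.frame(capped)))
  # under the cap nothing is dropped
  expect_equal(nrow(apply_cap(patches[1:30, ], spec, seed = 3)), 30L)
  # tallies never exceed the cap across random taggings
  set.seed(8)
  many <- data.frame(case_id = sample(c("a", "b"), 200, TRUE),
                     roi_id = 1L, x = seq_len(200), y = 0L,
                     classes = sample(c("1", "2", "1,2", "3,4"), 200, TRUE),
                     stringsAsFactors = FALSE)
  tally <- attr(apply_cap(many, patch_spec(64, 64, per_case_class_cap = 20L),
                          seed = 1), "class_tally")
  expect_true(all(tally <= 20L))
})

test_that("patch sets round-trip through CSV and feed training windows", {
  rois <- tiny_cohort()
  ps <- build_patchset(rois, patch_spec(48, 24), seed = 1)
  expect_true(all(ps$x + 48 <= 96 & ps$y + 48 <= 96))
  path <- withr::local_tempfile(fileext = ".csv")
  write_patchset(ps, path)
  back <- read_patchset(path)
  expect_equal(back$x, ps$x)
  expect_equal(back$classes, ps$classes)
})
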