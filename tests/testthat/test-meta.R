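printed_studies <- function(which = "main") {
  path <- system.file("extdata", "crossval_f1_printed.csv", package = "rpcseg")
  s <- utils::read.csv(path, stringsAsFactors = FALSE)
  s[s$analysis == which, c("label", "effect", "lower", "upper")]
}

test_that("standard errors reconstruct from printed confidence intervals", {
  expect_equal(ci_to_se(0.71, 0.65, 0.78), 0.13 / (2 * qnorm(0.975)),
               tolerance = 1e-12)
  expect_equal(ci_to_se(0.71, 0.65, 0.78), 0.03317, tolerance = 1e-3)
  expect_equal(ci_to_se(0.5, 0.5, 0.5), 0)
  expect_equal(ci_to_se(0.5, 0.4, 0.6, level = 0.90),
               0.2 / (2 * qnorm(0.95)))
  expect_error(ci_to_se(0.5, 0.7, 0.6), "inverted")
})

test_that("degenerate pooling cases behave analytically", {
  same <- data.frame(label = letters[1:4], effect = 0.7, se = 0.05)
  r <- meta_pool(same)
  expect_equal(r$mu, 0.7)
  expect_equal(r$tau2, 0)
  expect_equal(sum(r$weights), 1)

  two <- data.frame(label = c("a", "b"), effect = c(0.6, 0.8), se = 0.1)
  r2 <- meta_pool(two)
  expect_equal(r2$mu, 0.7)  # equal SEs: symmetric regardless of tau2

  expect_error(meta_pool(data.frame(label = "a", effect = 1, se = 0)),
               "> 0")
  expect_warning(one <- meta_pool(data.frame(label = "a", effect = 0.5,
                                             se = 0.1)), "single study")
  expect_equal(one$mu, 0.5)
})

test_that("REML and the pooled estimate agree with metafor across datasets", {
  skip_if_not_installed("metafor")
  set.seed(50)
  for (i in 1:20) {
    k <- sample(3:12, 1)
    se <- runif(k, 0.01, 0.1)
    y <- rnorm(k, 0.7, sqrt(se^2 + 0.004))
    ours <- meta_pool(data.frame(label = seq_len(k), effect = y, se = se))
    ref <- metafor::rma(yi = y, sei = se, method = "REML", test = "knha")
    expect_equal(ours$tau2, ref$tau2, tolerance = 1e-3)
    expect_equal(ours$mu, as.numeric(ref$b), tolerance = 1e-4)
    expect_equal(ours$i2, ref$I2, tolerance = 1e-2)
    # our root should attain at least metafor's restricted likelihood
    rll <- function(t2) {
      v <- se^2; w <- 1 / (v + t2); mu <- sum(w * y) / sum(w)
      -0.5 * sum(log(v + t2)) - 0.5 * log(sum(w)) -
        0.5 * sum(w * (y - mu)^2)
    }
    expect_gte(rll(ours$tau2), rll(ref$tau2) - 1e-10)
  }
})

test_that("with no heterogeneity the pooled mean matches the fixed-effect form", {
  set.seed(51)
  se <- runif(5, 0.05, 0.1)
  y <- rep(0.75, 5)  # zero spread forces tau2 to 0
  r <- meta_pool(data.frame(label = 1:5, effect = y, se = se))
  fe <- rpcseg:::fixed_effect_pool(y, se)
  expect_equal(r$tau2, 0)
  expect_equal(r$mu, fe$mu)
})

test_that("the pooled mean is a convex combination of the study effects", {
  set.seed(52)
  for (i in 1:50) {
    k <- sample(2:10, 1)
    y <- runif(k); se <- runif(k, 0.01, 0.3)
    r <- meta_pool(data.frame(label = 1:k, effect = y, se = se))
    expect_gte(r$mu, min(y))
    expect_lte(r$mu, max(y))
  }
})

test_that("HKSJ with the Jackson floor is never narrower than the Wald interval", {
  s <- printed_studies("main")
  r <- meta_pool(s)
  wald_half <- qnorm(0.975) * sqrt(1 / sum(1 / (ci_to_se(s$effect, s$lower,
                                                         s$upper)^2 + r$tau2)))
  expect_gte(unname(r$ci["upper"] - r$ci["lower"]), 2 * wald_half)
  expect_true(r$ci["lower"] <= r$mu && r$mu <= r$ci["upper"])
})

test_that("HKSJ variance matches a hand computation at k = 2", {
  y <- c(0.5, 0.7); se <- c(0.1, 0.1)
  r <- meta_pool(data.frame(label = c("a", "b"), effect = y, se = se))
  w <- 1 / (se^2 + r$tau2)
  mu <- sum(w * y) / sum(w)
  q <- sum(w * (y - mu)^2) / 1
  var_mu <- max(q, 1) / sum(w)
  expect_equal(r$mu, mu)
  expect_equal(unname(r$ci["upper"]), mu + qt(0.975, 1) * sqrt(var_mu))
  expect_equal(unname(r$ci["lower"]), mu - qt(0.975, 1) * sqrt(var_mu))
})

test_that("the Q-profile interval brackets the REML tau2 point estimate", {
  s <- printed_studies("main")
  r <- meta_pool(s)
  expect_gte(r$tau2, r$tau2_ci[["lower"]])
  expect_lte(r$tau2, r$tau2_ci[["upper"]])
})

test_that("REML recovers a known between-study variance on simulated sets", {
  set.seed(53)
  for (tau2 in c(0.001, 0.01)) {
    est <- replicate(300, {
      k <- 10
      se <- runif(k, 0.02, 0.06)
      y <- rnorm(k, 0.75, sqrt(se^2 + tau2))
      rpcseg:::reml_tau2(y, se^2)$tau2
    })
    expect_lt(abs(mean(est) - tau2), 0.35 * tau2 + 5e-4)
  }
})

test_that("study CSVs validate and meta results serialize", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(label = c("a", "b"), effect = c(0.7, NA),
                       se = c(0.1, 0.1)), path, row.names = FALSE)
  expect_error(read_studies(path), "malformed study row")

  r <- meta_pool(printed_studies("main"))
  out <- withr::local_tempfile(fileext = ".json")
  write_meta_result(r, out)
  back <- jsonlite::read_json(out, simplifyVector = TRUE)
  expect_equal(back$mu, r$mu, tolerance = 1e-12)
  fd <- forest_data(r)
  expect_equal(nrow(fd), 5L)
  expect_true(fd$pooled[5])
})
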