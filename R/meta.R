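#' Reconstruct a standard error from a printed confidence interval
#'
#' Assumes a symmetric normal interval: `se = (upper - lower) / (2 * z)`
#' with `z` the standard-normal quantile for the level.
#'
#' @param mean Point estimate (checked against the bounds).
#' @param lower,upper Interval bounds.
#' @param level Confidence level of the printed interval.
#' @return The standard error.
#' @examples
#' ci_to_se(0.71, 0.65, 0.78)  # ~0.03317
#' @export
ci_to_se <- function(mean, lower, upper, level = 0.95) {
  if (any(lower > upper)) stop("inverted CI bounds: lower > upper")
  if (any(mean < lower | mean > upper)) {
    stop("mean outside its CI; check the inputs")
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  (upper - lower) / (2 * z)
}

# REML estimate of the between-study variance for the intercept-only
# random-effects model, by Fisher scoring:
#   w_i = 1/(v_i + tau2),  mu = sum(w y)/sum(w),  P y = w (y - mu)
#   score     = -tr(P)/2 + y'PPy/2
#   E[inform] = tr(PP)/2
#   tau2 <- tau2 + (y'PPy - tr(P)) / tr(PP),  floored at 0
reml_tau2 <- function(y, v, tol = 1e-10, max_iter = 100L) {
  k <- length(y)
  # DerSimonian-Laird start
  w0 <- 1 / v
  mu0 <- sum(w0 * y) / sum(w0)
  Q <- sum(w0 * (y - mu0)^2)
  tau2 <- max(0, (Q - (k - 1)) / (sum(w0) - sum(w0^2) / sum(w0)))
  for (it in seq_len(max_iter)) {
    w <- 1 / (v + tau2)
    sw <- sum(w)
    mu <- sum(w * y) / sw
    trP <- sw - sum(w^2) / sw
    trPP <- sum(w^2) - 2 * sum(w^3) / sw + (sum(w^2) / sw)^2
    yPPy <- sum(w^2 * (y - mu)^2)
    delta <- (yPPy - trP) / trPP
    tau2_new <- max(0, tau2 + delta)
    if (abs(tau2_new - tau2) < tol) {
      return(list(tau2 = tau2_new, iterations = it, converged = TRUE))
    }
    tau2 <- tau2_new
  }
  list(tau2 = tau2, iterations = max_iter, converged = FALSE)
}

# Q-profile CI for tau2: invert the generalized Q statistic
#   Q(tau2) = sum w_i(tau2) (y_i - mu(tau2))^2,  w_i = 1/(v_i + tau2)
# against chi-square(k-1) quantiles.
tau2_qprofile_ci <- function(y, v, level = 0.95, tau2_max = 100) {
  k <- length(y)
  qgen <- function(tau2) {
    w <- 1 / (v + tau2)
    mu <- sum(w * y) / sum(w)
    sum(w * (y - mu)^2)
  }
  a <- (1 - level) / 2
  q_hi <- stats::qchisq(1 - a, df = k - 1)  # defines the lower bound
  q_lo <- stats::qchisq(a, df = k - 1)      # defines the upper bound
  lower <- if (qgen(0) <= q_hi) 0 else
    stats::uniroot(function(t) qgen(t) - q_hi, c(0, tau2_max))$root
  upper <- if (qgen(tau2_max) >= q_lo) tau2_max else if (qgen(0) <= q_lo) 0 else
    stats::uniroot(function(t) qgen(t) - q_lo, c(0, tau2_max))$root
  c(lower = lower, upper = upper)
}

#' Random-effects meta-analytic pooling
#'
#' Pools study effects (here: per-scanner mean F1 scores) under the
#' intercept-only random-effects model. The between-study variance tau^2 is
#' estimated by iterative restricted maximum likelihood (Fisher scoring,
#' tolerance 1e-10, at most 100 iterations, floored at 0); the pooled mean
#' is the inverse-variance weighted average with weights
#' `1 / (se_i^2 + tau^2)`. The confidence interval uses the
#' Hartung-Knapp-Sidik-Jonkman small-sample correction with a Jackson-type
#' variance floor: the HKSJ scaling factor
#' `q = sum(w (y - mu)^2) / (k - 1)` is floored at 1, so the corrected
#' interval is never narrower than the unmodified Wald random-effects
#' interval, and the `t(k-1)` quantile replaces the normal one.
#' Heterogeneity is summarized by Cochran's Q, by
#' `I^2 = 100 * tau^2 / (tau^2 + s^2)` with the typical within-study
#' variance `s^2 = (k-1) * sum(wt) / ((sum(wt))^2 - sum(wt^2))`,
#' `wt_i = 1/se_i^2`, and by a Q-profile CI for tau^2.
#'
#' @param studies data.frame with columns `label`, `effect` and either `se`
#'   or `lower`+`upper` (95% CI bounds, converted via [ci_to_se()]).
#' @param level Confidence level.
#' @return A `meta_result`: `mu`, `ci`, `se_mu`, `tau2`, `tau2_ci`, `i2`,
#'   `q`, `weights` (normalized to sum to 1), `k`, and the study table.
#' @examples
#' studies <- data.frame(
#'   label = c("philips", "leica", "3dhistech", "hamamatsu"),
#'   effect = c(0.81, 0.71, 0.76, 0.80),
#'   lower = c(0.77, 0.65, 0.72, 0.78),
#'   upper = c(0.84, 0.78, 0.80, 0.83))
#' meta_pool(studies)  # pooled mean rounds to 0.78
#' @export
meta_pool <- function(studies, level = 0.95) {
  stopifnot(is.data.frame(studies), all(c("label", "effect") %in% names(studies)))
  y <- as.numeric(studies$effect)
  if (!("se" %in% names(studies)) || all(is.na(studies$se))) {
    if (!all(c("lower", "upper") %in% names(studies))) {
      stop("studies need either an 'se' column or 'lower'/'upper' CI bounds")
    }
    se <- ci_to_se(y, as.numeric(studies$lower), as.numeric(studies$upper),
                   level = level)
  } else {
    se <- as.numeric(studies$se)
  }
  if (any(se <= 0)) stop("all study standard errors must be > 0")
  k <- length(y)
  if (k == 1L) {
    warning("single study: returning it unpooled")
    return(structure(list(mu = y, ci = c(lower = y - stats::qnorm(0.975) * se,
                                         upper = y + stats::qnorm(0.975) * se),
                          se_mu = se, tau2 = 0,
                          tau2_ci = c(lower = 0, upper = 0),
                          i2 = 0, q = 0, weights = 1, k = 1L,
                          studies = data.frame(label = studies$label,
                                               effect = y, se = se)),
                     class = "meta_result"))
  }
  v <- se^2
  fit <- reml_tau2(y, v)
  tau2 <- fit$tau2
  w <- 1 / (v + tau2)
  mu <- sum(w * y) / sum(w)

  # HKSJ variance with the Jackson-type floor q* = max(q, 1)
  q_hk <- sum(w * (y - mu)^2) / (k - 1)
  var_mu <- max(q_hk, 1) / sum(w)
  tq <- stats::qt(1 - (1 - level) / 2, df = k - 1)
  ci <- c(lower = mu - tq * sqrt(var_mu), upper = mu + tq * sqrt(var_mu))

  wt <- 1 / v
  mu_fe <- sum(wt * y) / sum(wt)
  Q <- sum(wt * (y - mu_fe)^2)
  s2 <- (k - 1) * sum(wt) / (sum(wt)^2 - sum(wt^2))
  i2 <- 100 * tau2 / (tau2 + s2)

  structure(list(mu = mu, ci = ci, se_mu = sqrt(var_mu), tau2 = tau2,
                 tau2_ci = tau2_qprofile_ci(y, v, level),
                 i2 = i2, q = Q, hk_scale = q_hk,
                 weights = w / sum(w), k = k,
                 reml_iterations = fit$iterations,
                 reml_converged = fit$converged,
                 studies = data.frame(label = studies$label, effect = y,
                                      se = se)),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("<meta_result> k = %d: pooled %.4f (%.0f%% CI %.4f-%.4f)\n",
              x$k, x$mu, 95, x$ci["lower"], x$ci["upper"]))
  cat(sprintf("  tau2 = %.6f [%.4f-%.4f], I2 = %.1f%%, Q = %.3f\n",
              x$tau2, x$tau2_ci["lower"], x$tau2_ci["upper"], x$i2, x$q))
  invisible(x)
}

# closed-form fixed-effect pooling, used as the tau2 = 0 oracle
fixed_effect_pool <- function(y, se) {
  w <- 1 / se^2
  mu <- sum(w * y) / sum(w)
  list(mu = mu, se_mu = sqrt(1 / sum(w)))
}

#' Read study inputs from CSV and write a meta result as JSON
#'
#' The CSV needs columns `label`, `effect` and either `se` or
#' `lower`/`upper`.
#'
#' @param path Study CSV path.
#' @return data.frame of study inputs.
#' @export
read_studies <- function(path) {
  if (!file.exists(path)) stop("study file not found: ", path)
  s <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "effect")
  miss <- setdiff(need, names(s))
  if (length(miss) > 0L) {
    stop("study file missing column(s): ", paste(miss, collapse = ", "))
  }
  bad <- which(is.na(s$effect))
  if (length(bad) > 0L) {
    stop("malformed study row(s): ", paste(bad, collapse = ", "))
  }
  s
}

#' @rdname read_studies
#' @param result A `meta_result`.
#' @param out Output JSON path.
#' @export
write_meta_result <- function(result, out) {
  obj <- list(mu = result$mu, ci = as.list(result$ci), tau2 = result$tau2,
              tau2_ci = as.list(result$tau2_ci), i2 = result$i2,
              q = result$q, k = result$k,
              weights = stats::setNames(as.list(result$weights),
                                        result$studies$label))
  jsonlite::write_json(obj, out, auto_unbox = TRUE, digits = NA)
  invisible(out)
}

#' Forest-plot data for a meta result
#'
#' Per-study effect, CI and normalized weight plus the pooled summary row,
#' as a plain data.frame (plot rendering is out of scope).
#'
#' @param result A `meta_result`.
#' @return data.frame with columns `label`, `effect`, `lower`, `upper`,
#'   `weight`, `pooled`.
#' @export
forest_data <- function(result) {
  z <- stats::qnorm(0.975)
  rbind(
    data.frame(label = result$studies$label, effect = result$studies$effect,
               lower = result$studies$effect - z * result$studies$se,
               upper = result$studies$effect + z * result$studies$se,
               weight = as.numeric(result$weights), pooled = FALSE),
    data.frame(label = "RE pooled", effect = result$mu,
               lower = result$ci[["lower"]], upper = result$ci[["upper"]],
               weight = 1, pooled = TRUE)
  )
}
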