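#' Score a case: per-class pixel-level F1
#'
#' One-vs-rest confusion counts pooled at pixel level over all ROIs of the
#' case; `F1 = 2TP / (2TP + FP + FN)` per class. Pixels whose truth is the
#' ignore code are excluded from every count. A class absent from both
#' truth and prediction has an undefined F1 (`NA`) and is excluded from
#' averages. The headline score is the cancer-class F1.
#'
#' @param prediction Predicted mask, `stitched_prediction`, or a list of
#'   either (multiple ROIs of one case).
#' @param truth Ground-truth mask or list of masks, aligned with
#'   `prediction`.
#' @param case_id,scanner_type Provenance carried into the result.
#' @return A `case_score`: per-class `f1`, `headline` (cancer F1),
#'   `macro_f1` (mean over defined classes), and a counts matrix with TP,
#'   FP, FN per class.
#' @export
score_case <- function(prediction, truth, case_id = "case",
                       scanner_type = NA_character_) {
  as_mask <- function(x) {
    if (inherits(x, "stitched_prediction")) x$labels else x
  }
  preds <- if (is.list(prediction) && !inherits(prediction, "stitched_prediction"))
    lapply(prediction, as_mask) else list(as_mask(prediction))
  truths <- if (is.list(truth)) truth else list(truth)
  stopifnot(length(preds) == length(truths))

  codes <- unname(RPC_TARGET_CODES)
  counts <- matrix(0, length(codes), 3,
                   dimnames = list(names(RPC_TARGET_CODES),
                                   c("tp", "fp", "fn")))
  for (i in seq_along(preds)) {
    p <- preds[[i]]; t <- truths[[i]]
    if (!identical(dim(p), dim(t))) {
      stop("prediction/truth shape mismatch: ",
           paste(dim(p), collapse = "x"), " vs ",
           paste(dim(t), collapse = "x"))
    }
    keep <- t != RPC_IGNORE_CODE
    pv <- p[keep]; tv <- t[keep]
    for (k in seq_along(codes)) {
      cd <- codes[k]
      counts[k, "tp"] <- counts[k, "tp"] + sum(pv == cd & tv == cd)
      counts[k, "fp"] <- counts[k, "fp"] + sum(pv == cd & tv != cd)
      counts[k, "fn"] <- counts[k, "fn"] + sum(pv != cd & tv == cd)
    }
  }
  denom <- 2 * counts[, "tp"] + counts[, "fp"] + counts[, "fn"]
  f1 <- ifelse(denom > 0, 2 * counts[, "tp"] / denom, NA_real_)
  structure(list(case_id = case_id, scanner_type = scanner_type,
                 f1 = f1, headline = unname(f1["cancer"]),
                 macro_f1 = mean(f1, na.rm = TRUE), counts = counts),
            class = "case_score")
}

#' @export
print.case_score <- function(x, ...) {
  cat(sprintf("<case_score> %s (%s): cancer F1 = %s\n", x$case_id,
              x$scanner_type,
              ifelse(is.na(x$headline), "undefined",
                     sprintf("%.3f", x$headline))))
  invisible(x)
}

#' Summarize per-case scores for one scanner
#'
#' Mean headline (cancer-class) F1 over cases with a t-based 95% CI:
#' `mean +/- t(n-1, 0.975) * SD / sqrt(n)`. With fewer than 2 cases the
#' summary is returned without a CI and flagged.
#'
#' @param scores List of `case_score`.
#' @param scanner_type Label for the summary (defaults to the scores').
#' @param level Confidence level.
#' @return A `scanner_summary`: `scanner_type`, `n`, `mean_f1`, `ci`
#'   (lower, upper or NA), per-class mean F1s, per-case headline F1s.
#' @export
summarize_scanner <- function(scores, scanner_type = NULL, level = 0.95) {
  stopifnot(length(scores) >= 1L)
  headline <- vapply(scores, function(s) s$headline, numeric(1))
  if (anyNA(headline)) {
    warning("dropping ", sum(is.na(headline)),
            " case(s) with undefined cancer F1")
    scores <- scores[!is.na(headline)]
    headline <- headline[!is.na(headline)]
  }
  n <- length(headline)
  if (is.null(scanner_type)) scanner_type <- scores[[1]]$scanner_type
  per_class <- rowMeans(vapply(scores, function(s) s$f1,
                               numeric(length(RPC_TARGET_CODES))),
                        na.rm = TRUE)
  m <- mean(headline)
  if (n >= 2L) {
    half <- stats::qt(1 - (1 - level) / 2, df = n - 1) *
      stats::sd(headline) / sqrt(n)
    ci <- c(lower = m - half, upper = m + half)
    flagged <- FALSE
  } else {
    ci <- c(lower = NA_real_, upper = NA_real_)
    flagged <- TRUE
  }
  structure(list(scanner_type = scanner_type, n = n, mean_f1 = m, ci = ci,
                 level = level, per_class = per_class, case_f1 = headline,
                 no_ci = flagged),
            class = "scanner_summary")
}

#' @export
print.scanner_summary <- function(x, ...) {
  ci_txt <- if (x$no_ci) "no CI (n < 2)" else
    sprintf("%.0f%% CI %.3f-%.3f", 100 * x$level, x$ci["lower"], x$ci["upper"])
  cat(sprintf("<scanner_summary> %s: mean F1 %.3f (%s), n = %d\n",
              x$scanner_type, x$mean_f1, ci_txt, x$n))
  invisible(x)
}

#' Write per-case scores and scanner summaries as CSV
#' @param scores List of `case_score`.
#' @param path Output CSV.
#' @return `path`, invisibly.
#' @export
write_case_scores <- function(scores, path) {
  rows <- lapply(scores, function(s) {
    data.frame(case_id = s$case_id, scanner_type = s$scanner_type,
               t(stats::setNames(s$f1, paste0("f1_", names(s$f1)))),
               headline_f1 = s$headline, macro_f1 = s$macro_f1)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
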