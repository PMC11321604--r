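#' Leave-one-scanner-out cross-validation plan
#'
#' For each scanner type present in the manifest, one fold: that scanner's
#' cases are the test set and all other scanners' cases the training set
#' (internal-external cross-validation, scanners standing in for external
#' cohorts).
#'
#' @param manifest Cohort manifest data.frame.
#' @param normalize,augment Ablation flags applied to every fold.
#' @return A `crossval_plan`: list of folds (`scanner`, `train_cases`,
#'   `test_cases`) plus the flags.
#' @export
crossval_plan <- function(manifest, normalize = TRUE, augment = TRUE) {
  validate_manifest(manifest)
  scanner_of <- tapply(manifest$scanner_type, manifest$case_id,
                       function(s) s[1])
  scanners <- unique(manifest$scanner_type)
  if (length(scanners) < 2L) {
    stop("need >= 2 scanner types for leave-one-scanner-out cross-validation")
  }
  folds <- lapply(scanners, function(sc) {
    test <- names(scanner_of)[scanner_of == sc]
    list(scanner = sc,
         train_cases = setdiff(names(scanner_of), test),
         test_cases = test)
  })
  names(folds) <- scanners
  for (f in folds) {
    stopifnot(length(intersect(f$train_cases, f$test_cases)) == 0L)
  }
  structure(list(folds = folds, normalize = normalize, augment = augment),
            class = "crossval_plan")
}

#' Run leave-one-scanner-out cross-validation
#'
#' For every fold of the plan: build a balanced patch set from the training
#' cases, train the model, run stitched inference on each test case, score
#' it against ground truth, and summarize the fold as a per-scanner mean F1
#' with its t-based CI. A final model trained on all cases is also
#' returned, and the per-fold means (with `se = SD/sqrt(n)`) are pooled by
#' random-effects meta-analysis when every fold has at least 2 test cases.
#'
#' @param rois List of `annotated_roi` (the whole cohort).
#' @param plan A `crossval_plan`.
#' @param pspec A `patch_spec` for training patch extraction.
#' @param config A `train_config` template; the plan's normalize/augment
#'   flags override its own, and fold `i` trains with seed
#'   `config$seed + i`.
#' @param keep_models Keep each fold's trained model in the result.
#' @param final_model Also train the all-data final model (skip to halve the
#'   runtime when only the fold summaries are needed).
#' @return An `rpc_crossval`: `summaries` (one `scanner_summary` per fold),
#'   `scores` (per-case `case_score`s), `meta` (a `meta_result` or NULL),
#'   `final_model`.
#' @export
run_crossval <- function(rois, plan, pspec = patch_spec(),
                         config = train_config(), keep_models = FALSE,
                         final_model = TRUE) {
  stopifnot(inherits(plan, "crossval_plan"))
  config$normalize <- plan$normalize
  config$augment <- plan$augment
  case_of <- vapply(rois, function(r) r$case_id, character(1))

  train_on <- function(cases, seed) {
    idx <- which(case_of %in% cases)
    sub <- rois[idx]
    ps <- build_patchset(sub, pspec, seed = seed)
    cfg <- config; cfg$seed <- seed
    train(ps, sub, cfg)
  }

  summaries <- list(); all_scores <- list(); models <- list()
  for (i in seq_along(plan$folds)) {
    fold <- plan$folds[[i]]
    if (length(fold$test_cases) == 0L) {
      warning("scanner ", fold$scanner, " has no test cases; fold skipped")
      next
    }
    model <- train_on(fold$train_cases, seed = config$seed + i)
    sspec <- stitch_spec(model$patch_size, model$patch_size %/% 2L)
    scores <- lapply(fold$test_cases, function(case) {
      case_rois <- rois[case_of == case]
      preds <- lapply(case_rois, function(r) predict_roi(model, r, sspec)$labels)
      truths <- lapply(case_rois, function(r) r$mask)
      score_case(preds, truths, case_id = case,
                 scanner_type = fold$scanner)
    })
    summaries[[fold$scanner]] <- summarize_scanner(scores, fold$scanner)
    all_scores <- c(all_scores, scores)
    if (keep_models) models[[fold$scanner]] <- model
  }

  final <- if (final_model) train_on(unique(case_of), seed = config$seed)
           else NULL

  meta <- NULL
  ns <- vapply(summaries, function(s) s$n, integer(1))
  if (length(summaries) >= 2L && all(ns >= 2L)) {
    studies <- data.frame(
      label = vapply(summaries, function(s) s$scanner_type, character(1)),
      effect = vapply(summaries, function(s) s$mean_f1, numeric(1)),
      se = vapply(summaries,
                  function(s) stats::sd(s$case_f1) / sqrt(s$n), numeric(1)))
    if (all(studies$se > 0)) meta <- meta_pool(studies)
  }

  structure(list(summaries = summaries, scores = all_scores, meta = meta,
                 final_model = final, models = models, plan = plan),
            class = "rpc_crossval")
}

#' @export
print.rpc_crossval <- function(x, ...) {
  cat("<rpc_crossval>", length(x$summaries), "folds\n")
  for (s in x$summaries) print(s)
  if (!is.null(x$meta)) print(x$meta)
  invisible(x)
}

#' Tabulate cross-validation fold summaries
#' @param cv An `rpc_crossval`.
#' @return data.frame with one row per fold.
#' @export
crossval_table <- function(cv) {
  do.call(rbind, lapply(cv$summaries, function(s) {
    data.frame(scanner_type = s$scanner_type, n = s$n, mean_f1 = s$mean_f1,
               ci_lower = s$ci[["lower"]], ci_upper = s$ci[["upper"]])
  }))
}
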