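#' Patient-grouped cross-validation with median-of-4 ensembling
#'
#' The central fitting function of the framework. Patients are ranked by a
#' clinical factor, divided into `k` groups (contiguous "ordered" blocks
#' or round-robin "balanced" strides), and every ordered (test,
#' validation) group pair -- `k * (k - 1)` role allotments, 20 for the
#' default `k = 5` -- defines one training session of a logistic head on
#' frozen features with best-validation-AUROC checkpointing. Each test
#' group is then scored by its four validation-rotation heads: per test
#' patient, `n_test_per_patient` quasi-RGB images are drawn, each image's
#' four head scores are reduced to their median, and the patient score is
#' the mean of the per-image medians.
#'
#' Because groups partition patients (never images), no image of a
#' patient can reach more than one of the training/validation/test roles
#' within an allotment; this is asserted on every fold via
#' [check_leakage()] using the actually sampled image provenance.
#'
#' With the default random-projection extractor and augmentation disabled
#' the whole run is a pure function of `(cohort, factor, mode, seed)`.
#'
#' @param cohort An `eus_cohort`, already cropped (see
#'   [preprocess_cohort()]) if it carries raw frames.
#' @param factor Split factor: `"chr"`, `"age"`, `"bmi"`, `"sai"` or
#'   `"eda"` (the latter requires [simulate_endoscopists()] first).
#' @param mode Division manner, `"ordered"` or `"balanced"`.
#' @param k Number of patient groups (default 5).
#' @param extractor A frozen `eus_extractor` (default: seeded
#'   random-projection extractor matching the sampling target size).
#' @param config A [train_config()].
#' @param seed Global seed; every stage seed is derived from it.
#' @param division Optionally a precomputed [divide_groups()] result
#'   (overrides `factor`/`mode`).
#' @return An object of class `eus_cv`: `scores` (data frame with
#'   `test_group`, `patient_id`, `label`, `score`), `fold_auroc`, `heads`
#'   (all trained heads, named `t<test>_v<validation>`), `division`,
#'   `audits`, `n_sessions`, and the call configuration.
#' @seealso [summary.eus_cv()], [aggregate_folds()], [compare_fold_scores()]
#' @export
eus_crossval <- function(cohort, factor = "chr",
                         mode = c("ordered", "balanced"), k = 5,
                         extractor = NULL, config = train_config(),
                         seed = 1L, division = NULL) {
  stopifnot(inherits(cohort, "eus_cohort"))
  mode <- match.arg(mode)
  if (is.null(extractor))
    extractor <- random_projection_extractor(
      input_size = config$sampling$target,
      seed = derive_seed(seed, "extractor"))
  if (is.null(division)) {
    ranked <- order_patients(cohort, factor)
    division <- divide_groups(ranked, k = k, mode = mode, factor = factor)
  }
  k <- division$k
  allotments <- enumerate_allotments(k)

  use_cache <- inherits(extractor, "eus_rp_extractor") &&
    is.null(config$sampling$augment) &&
    extractor$input_size == config$sampling$target
  cache <- if (use_cache)
    build_frame_feature_cache(extractor, cohort$patients,
                              config$sampling$target)

  heads <- list()
  for (a in allotments) {
    cfg <- config
    cfg$seed <- derive_seed(seed, sprintf("train_t%d_v%d", a$test,
                                          a$validation))
    heads[[sprintf("t%d_v%d", a$test, a$validation)]] <-
      train_head(extractor,
                 patients_in_groups(cohort, division, a$training),
                 patients_in_groups(cohort, division, a$validation),
                 cfg, cache)
  }

  rows <- list(); audits <- list(); fold_auroc <- numeric(k)
  for (test in seq_len(k)) {
    vals <- setdiff(seq_len(k), test)
    fold_heads <- heads[sprintf("t%d_v%d", test, vals)]
    test_patients <- patients_in_groups(cohort, division, test)
    preds <- lapply(test_patients, function(p)
      predict_patient(fold_heads, extractor, p, config$sampling,
                      seed = derive_seed(seed, paste0("test_", p$patient_id)),
                      cache = cache))
    rows[[test]] <- data.frame(
      test_group = test,
      patient_id = vapply(preds, `[[`, character(1), "patient_id"),
      label = vapply(preds, `[[`, integer(1), "label"),
      score = vapply(preds, `[[`, numeric(1), "score"),
      stringsAsFactors = FALSE)
    fold_auroc[test] <- if (length(unique(rows[[test]]$label)) == 2L)
      auroc(rows[[test]]$score, rows[[test]]$label) else NA_real_
    # leakage audit per allotment, from the actually sampled provenance
    for (v in vals) {
      h <- heads[[sprintf("t%d_v%d", test, v)]]
      batches <- rbind(
        data.frame(patient_id = h$patients_seen$training, role = "training",
                   stringsAsFactors = FALSE),
        data.frame(patient_id = h$patients_seen$validation,
                   role = "validation", stringsAsFactors = FALSE),
        data.frame(patient_id = rows[[test]]$patient_id, role = "test",
                   stringsAsFactors = FALSE))
      rep_ <- check_leakage(division,
                            list(test = test, validation = v,
                                 training = setdiff(seq_len(k), c(test, v))),
                            batches)
      if (!rep_$pass)
        stop(sprintf("information leakage detected (test %d, validation %d): %s",
                     test, v, paste(rep_$offenders, collapse = ", ")),
             call. = FALSE)
      audits[[sprintf("t%d_v%d", test, v)]] <- rep_
    }
  }
  structure(list(scores = do.call(rbind, rows), fold_auroc = fold_auroc,
                 heads = heads, division = division, audits = audits,
                 n_sessions = length(allotments), factor = division$factor,
                 mode = division$mode, k = k, seed = seed,
                 extractor_name = extractor$name, config = config),
            class = "eus_cv")
}

#' @export
print.eus_cv <- function(x, ...) {
  cat(sprintf("Patient-grouped %d-fold cross-validation (factor %s, %s division)\n",
              x$k, toupper(x$factor), x$mode))
  cat(sprintf("  %d training sessions on '%s' features, seed %d\n",
              x$n_sessions, x$extractor_name, x$seed))
  cat(sprintf("  per-fold test AUROC: %s   (mean %.3f)\n",
              paste(sprintf("%.3f", x$fold_auroc), collapse = " "),
              mean(x$fold_auroc, na.rm = TRUE)))
  invisible(x)
}

#' Per-fold and mean evaluation of a cross-validation run
#'
#' Computes patient-level AUROC and threshold-0.5 confusion metrics for
#' each test group and their unweighted mean across folds.
#'
#' @param object An `eus_cv`.
#' @param threshold Decision threshold (default 0.5; a score at the
#'   threshold is called positive).
#' @param ... Unused.
#' @return A list of class `summary.eus_cv` with `per_fold` (data frame)
#'   and `mean` (named numeric vector; undefined PPV/NPV folds excluded
#'   with a flag).
#' @export
summary.eus_cv <- function(object, threshold = 0.5, ...) {
  folds <- lapply(seq_len(object$k), function(g) {
    sc <- object$scores[object$scores$test_group == g, ]
    confusion_metrics(sc$score, sc$label, threshold)
  })
  per_fold <- data.frame(
    fold = seq_len(object$k),
    auroc = vapply(folds, function(m) m$auroc, numeric(1)),
    accuracy = vapply(folds, function(m) m$accuracy, numeric(1)),
    sensitivity = vapply(folds, function(m) m$sensitivity, numeric(1)),
    specificity = vapply(folds, function(m) m$specificity, numeric(1)),
    ppv = vapply(folds, function(m) m$ppv, numeric(1)),
    npv = vapply(folds, function(m) m$npv, numeric(1)))
  agg <- if (object$k == 5L) aggregate_folds(folds) else NULL
  structure(list(per_fold = per_fold, mean = agg, factor = object$factor,
                 mode = object$mode, threshold = threshold),
            class = "summary.eus_cv")
}

#' @export
print.summary.eus_cv <- function(x, ...) {
  cat(sprintf("Cross-validation summary (factor %s, %s division, threshold %.2f)\n",
              toupper(x$factor), x$mode, x$threshold))
  print(cbind(x$per_fold[1], round(x$per_fold[-1], 3)), row.names = FALSE)
  if (!is.null(x$mean)) {
    cat("mean over folds:\n")
    print(round(x$mean$mean, 3))
    if (length(x$mean$incomplete))
      cat("  (", paste(x$mean$incomplete, collapse = ", "),
          "averaged over defined folds only )\n")
  }
  invisible(x)
}

#' ROC curves of a cross-validation run
#'
#' Plots the per-fold empirical ROC curves of the patient-level ensemble
#' scores, with the chance diagonal.
#'
#' @param x An `eus_cv`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.eus_cv <- function(x, ...) {
  graphics::plot(c(0, 1), c(0, 1), type = "l", lty = 3, col = "grey50",
                 xlab = "false positive rate", ylab = "true positive rate",
                 main = sprintf("ROC by test group (%s, %s)",
                                toupper(x$factor), x$mode), ...)
  for (g in seq_len(x$k)) {
    sc <- x$scores[x$scores$test_group == g, ]
    r <- roc_points(sc$score, sc$label)
    graphics::lines(r$fpr, r$tpr, col = g)
  }
  graphics::legend("bottomright", bty = "n", col = seq_len(x$k), lty = 1,
                   legend = sprintf("fold %d (AUROC %.2f)", seq_len(x$k),
                                    x$fold_auroc))
  invisible(x)
}

# Empirical ROC curve points (thresholds descending).
roc_points <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(labels[ord] == 1L); fp <- cumsum(labels[ord] == 0L)
  keep <- !duplicated(scores[ord], fromLast = TRUE)
  list(fpr = c(0, fp[keep] / max(1, sum(labels == 0L))),
       tpr = c(0, tp[keep] / max(1, sum(labels == 1L))))
}
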