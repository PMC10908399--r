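#' Training configuration for the classification head
#'
#' The head is a single linear layer with a logistic link, trained by
#' plain minibatch stochastic gradient descent on the logistic loss; only
#' the head is trained, the feature extractor stays frozen. After every
#' epoch the validation AUROC is computed on a fixed seeded sample of
#' quasi-RGB images from the validation patients, and the parameters of
#' the epoch with the best validation AUROC (earliest on ties) are kept.
#'
#' @param epochs Number of training epochs (default 20).
#' @param learning_rate SGD step size (default 0.5).
#' @param batch_size Minibatch size (default 32).
#' @param n_val_per_class Validation images sampled per class, once per
#'   training session (default 100).
#' @param sampling A [sampling_config()] governing epoch and test-time
#'   image sampling.
#' @param seed Integer seed of the training session.
#' @return A list of class `eus_train_config`.
#' @export
train_config <- function(epochs = 20, learning_rate = 0.5, batch_size = 32,
                         n_val_per_class = 100,
                         sampling = sampling_config(), seed = 1L) {
  if (epochs < 1) abort_field("epochs", "must be >= 1")
  if (learning_rate <= 0) abort_field("learning_rate", "must be positive")
  if (batch_size < 1) abort_field("batch_size", "must be >= 1")
  structure(list(epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 n_val_per_class = as.integer(n_val_per_class),
                 sampling = sampling, seed = as.integer(seed)),
            class = "eus_train_config")
}

# Earliest epoch attaining the maximal validation AUROC.
select_best_epoch <- function(val_aurocs) {
  which.max(val_aurocs)  # which.max returns the first maximum
}

# AUROC that degrades to 0.5 instead of erroring when only one class is
# present (degenerate validation samples; see the methods vignette).
safe_auroc <- function(scores, labels) {
  if (length(unique(labels)) < 2L) return(0.5)
  auroc(scores, labels)
}

# Validation image plan: class-balanced when both classes are present in
# the validation group, otherwise an even spread over its patients.
validation_plan <- function(val_patients, config) {
  scfg <- config$sampling
  scfg$n_per_epoch <- max(2L, 2L * config$n_val_per_class)
  seed <- derive_seed(config$seed, "validation")
  labels <- vapply(val_patients, `[[`, integer(1), "label")
  if (length(unique(labels)) == 2L)
    return(sample_epoch_plan(val_patients, scfg, seed))
  with_seed(seed, {
    plans <- lapply(val_patients, function(p) {
      n_i <- scfg$n_per_epoch %/% length(val_patients)
      if (n_i < 1L) n_i <- 1L
      pl <- replicate(n_i, sample_quasi_triple(p, scfg$same_video_only),
                      simplify = FALSE)
      data.frame(patient_id = p$patient_id, label = p$label,
                 video_1 = vapply(pl, function(t) t$video[1], ""),
                 video_2 = vapply(pl, function(t) t$video[2], ""),
                 video_3 = vapply(pl, function(t) t$video[3], ""),
                 idx_1 = vapply(pl, function(t) t$index[1], 0L),
                 idx_2 = vapply(pl, function(t) t$index[2], 0L),
                 idx_3 = vapply(pl, function(t) t$index[3], 0L),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, plans)
  })
}

#' Train a classification head on frozen features
#'
#' Runs `epochs` training epochs; each epoch draws a fresh class-balanced
#' sample of quasi-RGB images from the training patients (see
#' [sample_epoch()]), extracts frozen features, and applies minibatch SGD
#' updates to the logistic head. After every epoch the AUROC on a fixed
#' seeded validation image sample is recorded, and the returned parameters
#' are those of the epoch with the highest validation AUROC (earliest
#' epoch on ties).
#'
#' @param extractor An `eus_extractor`.
#' @param train_patients Patient records of the training groups; both
#'   classes must be present.
#' @param val_patients Patient records of the validation group (non-empty).
#' @param config A [train_config()].
#' @param cache Optional per-frame feature cache built by the
#'   cross-validation driver; `NULL` extracts features directly.
#' @return An object of class `eus_head`: checkpointed `weights` and
#'   `bias` (those of `best_epoch`), `best_val_auroc`, the end-of-training
#'   parameters under `final`, a per-epoch `log` (epoch, train_loss,
#'   val_auroc), and the ids of the patients whose images were seen
#'   (`patients_seen$training`, `patients_seen$validation`).
#' @export
train_head <- function(extractor, train_patients, val_patients,
                       config = train_config(), cache = NULL) {
  stopifnot(inherits(extractor, "eus_extractor"))
  if (length(val_patients) == 0L)
    stop("validation patients must be non-empty", call. = FALSE)
  scfg <- config$sampling
  vplan <- validation_plan(val_patients, config)
  Xv <- plan_features(extractor, val_patients, vplan, scfg, cache)
  yv <- vplan$label

  d <- extractor$output_dim
  w <- numeric(d); b <- 0
  log_epoch <- numeric(config$epochs)
  log_loss <- numeric(config$epochs)
  log_val <- numeric(config$epochs)
  best <- list(val = -Inf, epoch = NA_integer_, w = w, b = b)
  train_ids <- character(0)

  for (e in seq_len(config$epochs)) {
    plan <- sample_epoch_plan(train_patients, scfg,
                              derive_seed(config$seed, sprintf("epoch_%d", e)))
    train_ids <- union(train_ids, unique(plan$patient_id))
    X <- plan_features(extractor, train_patients, plan, scfg, cache)
    y <- plan$label
    n <- nrow(X)
    ord <- with_seed(derive_seed(config$seed, sprintf("sgd_%d", e)),
                     sample(n))
    starts <- seq(1L, n, by = config$batch_size)
    for (s in starts) {
      idx <- ord[s:min(s + config$batch_size - 1L, n)]
      Xb <- X[idx, , drop = FALSE]
      p <- stats::plogis(drop(Xb %*% w) + b)
      g <- p - y[idx]
      w <- w - config$learning_rate * drop(crossprod(Xb, g)) / length(idx)
      b <- b - config$learning_rate * mean(g)
    }
    p_all <- stats::plogis(drop(X %*% w) + b)
    eps <- 1e-12
    log_loss[e] <- -mean(y * log(p_all + eps) + (1 - y) * log(1 - p_all + eps))
    log_val[e] <- safe_auroc(stats::plogis(drop(Xv %*% w) + b), yv)
    log_epoch[e] <- e
    if (log_val[e] > best$val) {
      best <- list(val = log_val[e], epoch = e, w = w, b = b)
    }
  }
  structure(list(weights = best$w, bias = best$b,
                 best_epoch = best$epoch, best_val_auroc = best$val,
                 final = list(weights = w, bias = b),
                 log = data.frame(epoch = log_epoch, train_loss = log_loss,
                                  val_auroc = log_val),
                 extractor_name = extractor$name, output_dim = d,
                 config = config,
                 patients_seen = list(training = sort(train_ids),
                                      validation = sort(unique(vplan$patient_id)))),
            class = "eus_head")
}

#' @export
print.eus_head <- function(x, ...) {
  cat(sprintf("Logistic head on frozen '%s' features (%d-d)\n",
              x$extractor_name, x$output_dim))
  cat(sprintf("  best validation AUROC %.3f at epoch %d of %d\n",
              x$best_val_auroc, x$best_epoch, nrow(x$log)))
  invisible(x)
}

#' @export
coef.eus_head <- function(object, ...) {
  c(bias = object$bias, stats::setNames(object$weights,
                                        paste0("f", seq_along(object$weights))))
}

#' Score images or feature rows with a trained head
#'
#' @param object An `eus_head`.
#' @param newdata Feature matrix (rows = images) or a list of
#'   `eus_quasi_rgb` images (then `extractor` is required).
#' @param extractor The frozen extractor used in training, when `newdata`
#'   are images.
#' @param ... Unused.
#' @return Numeric vector of scores in `[0, 1]` (probability of class 1).
#' @export
predict.eus_head <- function(object, newdata, extractor = NULL, ...) {
  X <- if (is.matrix(newdata)) newdata
  else {
    if (is.null(extractor))
      stop("provide 'extractor' to score images", call. = FALSE)
    extract_features(extractor, newdata)
  }
  stats::plogis(drop(X %*% object$weights) + object$bias)
}

#' Median-of-four ensemble
#'
#' The framework always trains four heads per test group (one per
#' validation rotation); their median -- for four values the mean of the
#' two middle ones -- is the final prediction. Permutation-invariant and
#' bounded by the member scores.
#'
#' @param scores Numeric vector of exactly four values in `[0, 1]`.
#' @return The median.
#' @export
ensemble_median <- function(scores) {
  if (length(scores) != 4L)
    stop(sprintf("ensemble expects exactly 4 member scores, got %d",
                 length(scores)), call. = FALSE)
  if (any(scores < 0 | scores > 1))
    stop("member scores must lie in [0, 1]", call. = FALSE)
  stats::median(scores)
}

#' Ensemble prediction for one test patient
#'
#' Generates `n_test_per_patient` quasi-RGB images of the patient, scores
#' each with the four heads, takes the per-image median-of-4, and returns
#' the mean of the per-image medians as the patient score.
#'
#' @param heads List of exactly four `eus_head` objects.
#' @param extractor The frozen extractor.
#' @param patient A patient record (must belong to the test group only).
#' @param config A [sampling_config()].
#' @param seed Integer seed or `NULL`.
#' @param cache Optional per-frame feature cache.
#' @return A list of class `eus_patient_prediction`: `score` (mean of
#'   medians, in `[0, 1]`), `medians`, `member_scores` (n x 4 matrix),
#'   `plan` (image provenance), `patient_id`, `label`.
#' @export
predict_patient <- function(heads, extractor, patient,
                            config = sampling_config(), seed = NULL,
                            cache = NULL) {
  if (length(heads) != 4L)
    stop("exactly 4 heads are required", call. = FALSE)
  plan <- sample_test_set(patient, config, seed, materialize = FALSE)
  cfg <- config; cfg$augment <- NULL
  X <- plan_features(extractor, list(patient), plan, cfg, cache)
  member <- vapply(heads, function(h) predict(h, X), numeric(nrow(X)))
  member <- matrix(member, nrow = nrow(X))
  medians <- apply(member, 1L, ensemble_median)
  structure(list(score = mean(medians), medians = medians,
                 member_scores = member, plan = plan,
                 patient_id = patient$patient_id, label = patient$label),
            class = "eus_patient_prediction")
}
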