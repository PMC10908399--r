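#' Experiment configuration
#'
#' Bundles every stage's settings into one reproducible record. Every
#' stochastic stage derives its own seed from the global seed and its
#' stage name via [derive_seed()], so adding a stage never perturbs the
#' randomness of the others.
#'
#' @param cohort A [cohort_spec()] (synthetic mode) or a directory path of
#'   an existing cohort (see [read_cohort()]).
#' @param factors Character vector of split factors to run.
#' @param modes Division manners to run for each factor.
#' @param k Number of patient groups.
#' @param crop An [crop_box()] or `NULL` for the cohort-derived default.
#' @param train A [train_config()].
#' @param extractor_dim Output dimension of the default random-projection
#'   extractor.
#' @param seed Global seed.
#' @param out_dir Output directory, or `NULL` to keep results in memory
#'   only.
#' @return A list of class `eus_run_config`.
#' @export
run_config <- function(cohort = cohort_spec(), factors = "chr",
                       modes = c("ordered", "balanced"), k = 5,
                       crop = NULL, train = train_config(),
                       extractor_dim = 64, seed = 1L, out_dir = NULL) {
  if (!inherits(cohort, "eus_cohort_spec") && !is.character(cohort))
    abort_field("cohort", "must be a cohort_spec() or a directory path")
  factors <- vapply(factors, factor_key, character(1), USE.NAMES = FALSE)
  modes <- match.arg(modes, c("ordered", "balanced"), several.ok = TRUE)
  if (!inherits(train, "eus_train_config"))
    abort_field("train", "must be a train_config()")
  structure(list(cohort = cohort, factors = factors, modes = modes,
                 k = as.integer(k), crop = crop, train = train,
                 extractor_dim = as.integer(extractor_dim),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "eus_run_config")
}

#' Run a full experiment
#'
#' Executes the whole pipeline: generate (or load) the cohort, simulate
#' the endoscopist panel, crop frames, and for every requested factor and
#' division manner run the patient-grouped cross-validation; then
#' assemble the cohort table, per-dataset summaries and ordered-versus-
#' balanced comparisons. With the default extractor the entire record is
#' a pure function of the configuration.
#'
#' @param config An [run_config()].
#' @return An object of class `eus_experiment`: `config`, `metadata`,
#'   `cohort_table`, `runs` (named `eus_cv` list), `comparisons`, and
#'   `version`. When `config$out_dir` is set, metadata, divisions,
#'   results CSV and the JSON summary are also written there.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "eus_run_config"))
  cohort <- if (is.character(config$cohort)) read_cohort(config$cohort)
  else {
    spec <- config$cohort
    spec$seed <- derive_seed(config$seed, "cohort")
    generate_cohort(spec)
  }
  if (is.null(attr(cohort, "panel")) && !is.null(cohort$spec))
    cohort <- simulate_endoscopists(cohort,
                                    seed = derive_seed(config$seed,
                                                       "endoscopists"))
  cohort <- preprocess_cohort(cohort, config$crop)
  meta <- as.data.frame(cohort)
  ctable <- cohort_table(meta,
                         continuous = c("age_years", "bmi",
                                        "alcohol_g_per_day"),
                         categorical = "alcohol_category")
  extractor <- random_projection_extractor(
    output_dim = config$extractor_dim,
    input_size = config$train$sampling$target,
    seed = derive_seed(config$seed, "extractor"))
  runs <- list()
  for (f in config$factors) for (m in config$modes) {
    runs[[paste0(f, "_", m)]] <-
      eus_crossval(cohort, factor = f, mode = m, k = config$k,
                   extractor = extractor, config = config$train,
                   seed = derive_seed(config$seed, paste0("cv_", f, "_", m)))
  }
  comparisons <- list()
  for (f in config$factors) {
    o <- runs[[paste0(f, "_ordered")]]; b <- runs[[paste0(f, "_balanced")]]
    if (!is.null(o) && !is.null(b)) comparisons[[f]] <- compare_modes(o, b)
  }
  record <- structure(list(config = config, metadata = meta,
                           cohort_table = ctable, runs = runs,
                           comparisons = comparisons,
                           version = as.character(utils::packageVersion("euscv"))),
                      class = "eus_experiment")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_metadata(meta, file.path(config$out_dir, "metadata.csv"))
    for (nm in names(runs))
      write_division(runs[[nm]]$division,
                     file.path(config$out_dir, paste0("division_", nm, ".csv")))
    write_results(runs, config$out_dir)
    save_run_config(config, file.path(config$out_dir, "config.yaml"))
  }
  record
}

#' @export
print.eus_experiment <- function(x, ...) {
  cat(sprintf("EUS cross-validation experiment (seed %d, %d dataset run%s)\n",
              x$config$seed, length(x$runs),
              if (length(x$runs) == 1L) "" else "s"))
  for (nm in names(x$runs))
    cat(sprintf("  %-14s mean test AUROC %.3f\n", nm,
                mean(x$runs[[nm]]$fold_auroc, na.rm = TRUE)))
  invisible(x)
}

#' Save / load an experiment configuration as YAML
#'
#' The YAML round-trip is lossless for every field needed to re-run the
#' experiment; `load_run_config()` rebuilds the classed configuration
#' objects.
#'
#' @param config An [run_config()].
#' @param path YAML file path.
#' @return `save_run_config()` returns `path` invisibly;
#'   `load_run_config()` returns an `eus_run_config`.
#' @export
save_run_config <- function(config, path) {
  stopifnot(inherits(config, "eus_run_config"))
  x <- unclass(config)
  if (inherits(x$cohort, "eus_cohort_spec")) {
    x$cohort <- unclass(x$cohort)
    x$cohort$covariate_params <- lapply(x$cohort$covariate_params, as.list)
  }
  if (!is.null(x$crop)) x$crop <- unclass(x$crop)
  tr <- unclass(x$train)
  tr$sampling <- unclass(tr$sampling)
  if (!is.null(tr$sampling$augment))
    tr$sampling$augment <- unclass(tr$sampling$augment)
  x$train <- tr
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname save_run_config
#' @export
load_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  cohort <- if (is.character(x$cohort)) x$cohort
  else cohort_spec(n_positive = x$cohort$n_positive,
                   n_negative = x$cohort$n_negative,
                   videos_per_patient = unlist(x$cohort$videos_per_patient),
                   frames_per_video = unlist(x$cohort$frames_per_video),
                   frame_height = x$cohort$frame_height,
                   frame_width = x$cohort$frame_width,
                   effect_size = x$cohort$effect_size,
                   covariate_params = lapply(x$cohort$covariate_params,
                                             function(v) unlist(v)),
                   n_experts = x$cohort$n_experts,
                   n_novices = x$cohort$n_novices,
                   confound = x$cohort$confound,
                   seed = x$cohort$seed)
  samp <- x$train$sampling
  augment <- if (!is.null(samp$augment))
    augment_config(samp$augment$hflip, samp$augment$max_rotate,
                   samp$augment$max_brightness)
  run_config(cohort = cohort, factors = x$factors, modes = x$modes,
             k = x$k,
             crop = if (!is.null(x$crop))
               crop_box(x$crop$top, x$crop$left, x$crop$height,
                        x$crop$width),
             train = train_config(epochs = x$train$epochs,
                                  learning_rate = x$train$learning_rate,
                                  batch_size = x$train$batch_size,
                                  n_val_per_class = x$train$n_val_per_class,
                                  sampling = sampling_config(
                                    n_per_epoch = samp$n_per_epoch,
                                    n_test_per_patient = samp$n_test_per_patient,
                                    same_video_only = samp$same_video_only,
                                    augment = augment,
                                    target = samp$target),
                                  seed = x$train$seed),
             extractor_dim = x$extractor_dim, seed = x$seed,
             out_dir = x$out_dir)
}
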