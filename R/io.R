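#' Write cohort metadata to CSV
#'
#' One row per patient with columns `patient_id`, `label`, `age_years`,
#' `bmi`, `alcohol_g_per_day`, `alcohol_category`, `session_date`,
#' `eda_score` and (for synthetic cohorts) `diagnosability`. Floats are
#' written with six significant digits.
#'
#' @param cohort An `eus_cohort` or a metadata data frame.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_metadata <- function(cohort, path) {
  meta <- if (inherits(cohort, "eus_cohort")) as.data.frame(cohort) else cohort
  num <- vapply(meta, is.numeric, logical(1))
  meta[num] <- lapply(meta[num], function(x) signif(x, 6))
  utils::write.csv(meta, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

metadata_required_cols <- c("patient_id", "label", "age_years", "bmi",
                            "alcohol_g_per_day", "alcohol_category",
                            "session_date", "eda_score")

#' Read and validate cohort metadata
#'
#' Rejects malformed files with messages naming the offending column, id
#' or line number (line 1 is the header).
#'
#' @param path CSV path as written by [write_metadata()].
#' @return A validated metadata data frame.
#' @export
read_metadata <- function(path) {
  meta <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(metadata_required_cols, names(meta))
  if (length(missing))
    stop(sprintf("metadata is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  dup <- meta$patient_id[duplicated(meta$patient_id)]
  if (length(dup))
    stop(sprintf("duplicate patient_id: %s",
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  bad <- which(!(meta$label %in% c(0L, 1L)))
  if (length(bad))
    stop(sprintf("label outside {0,1} at line %s",
                 paste(bad + 1L, collapse = ", ")), call. = FALSE)
  bad_cat <- which(!(meta$alcohol_category %in%
                       c("light", "moderate", "heavy")))
  if (length(bad_cat))
    stop(sprintf("invalid alcohol_category at line %s",
                 paste(bad_cat + 1L, collapse = ", ")), call. = FALSE)
  for (col in c("age_years", "bmi", "alcohol_g_per_day", "session_date")) {
    bad_num <- which(is.na(suppressWarnings(as.numeric(meta[[col]]))))
    if (length(bad_num))
      stop(sprintf("non-numeric '%s' at line %s", col,
                   paste(bad_num + 1L, collapse = ", ")), call. = FALSE)
  }
  meta
}

#' Write a cohort's frames and metadata to a directory
#'
#' Frames are written as 8-bit grayscale PNG files under
#' `patients/<patient_id>/videos/<video_id>/frame_<jjjj>.png` (`jjjj`
#' zero-padded, 0-based temporal index), plus `metadata.csv` at the root.
#'
#' @param cohort An `eus_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "eus_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_metadata(cohort, file.path(dir, "metadata.csv"))
  for (p in cohort$patients) {
    for (vname in names(p$videos)) {
      vdir <- file.path(dir, "patients", p$patient_id, "videos", vname)
      dir.create(vdir, recursive = TRUE, showWarnings = FALSE)
      frames <- p$videos[[vname]]
      for (j in seq_along(frames))
        png::writePNG(frames[[j]] / 255,
                      file.path(vdir, sprintf("frame_%04d.png", j - 1L)))
    }
  }
  invisible(dir)
}

#' Read a cohort from a directory of frames and metadata
#'
#' Inverse of [write_cohort()]: reads `metadata.csv` and every
#' `patients/<id>/videos/<vid>/frame_*.png` as 8-bit grayscale frames.
#'
#' @param dir Cohort directory.
#' @return An `eus_cohort` (without generator ground truth unless the
#'   metadata carries a `diagnosability` column).
#' @export
read_cohort <- function(dir) {
  meta <- read_metadata(file.path(dir, "metadata.csv"))
  patients <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    pid <- meta$patient_id[i]
    pdir <- file.path(dir, "patients", pid, "videos")
    vnames <- sort(list.dirs(pdir, recursive = FALSE, full.names = FALSE))
    if (!length(vnames))
      stop(sprintf("no videos found for patient %s", pid), call. = FALSE)
    videos <- lapply(vnames, function(v) {
      files <- sort(list.files(file.path(pdir, v), pattern = "^frame_.*\\.png$",
                               full.names = TRUE))
      lapply(files, function(f) {
        m <- png::readPNG(f)
        if (length(dim(m)) == 3L) m <- m[, , 1]
        matrix(as.integer(round(255 * m)), nrow(m), ncol(m))
      })
    })
    names(videos) <- vnames
    patients[[i]] <- list(
      patient_id = pid, label = as.integer(meta$label[i]),
      age = meta$age_years[i], bmi = meta$bmi[i],
      alcohol_g_per_day = meta$alcohol_g_per_day[i],
      alcohol_category = meta$alcohol_category[i],
      session_date = meta$session_date[i],
      eda_score = meta$eda_score[i],
      diagnosability = if ("diagnosability" %in% names(meta))
        meta$diagnosability[i] else NA_real_,
      truth = NULL, videos = videos)
  }
  structure(list(patients = patients, spec = NULL), class = "eus_cohort")
}

#' Write a division to CSV
#'
#' @param division An `eus_division`.
#' @param path Output CSV path (columns `patient_id`, `factor`, `mode`,
#'   `group`).
#' @return `path`, invisibly.
#' @export
write_division <- function(division, path) {
  utils::write.csv(data.frame(patient_id = names(division$assignment),
                              factor = division$factor,
                              mode = division$mode,
                              group = unname(division$assignment)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a division from CSV
#'
#' @param path CSV path as written by [write_division()].
#' @return An `eus_division`. The ranked order is recovered from the file
#'   row order (rows are written in rank order).
#' @export
read_division <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("patient_id", "factor", "mode", "group"), names(d))
  if (length(missing))
    stop(sprintf("division file missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  structure(list(assignment = stats::setNames(as.integer(d$group),
                                              d$patient_id),
                 ranked = d$patient_id, k = max(d$group),
                 mode = d$mode[1], factor = d$factor[1]),
            class = "eus_division")
}

#' Serialize a trained head to JSON
#'
#' @param head An `eus_head`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_head <- function(head, path) {
  jsonlite::write_json(list(weights = head$weights, bias = head$bias,
                            best_epoch = head$best_epoch,
                            best_val_auroc = head$best_val_auroc,
                            output_dim = head$output_dim,
                            extractor = head$extractor_name,
                            seed = head$config$seed),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write cross-validation results of an experiment
#'
#' Writes `results.csv` (one row per fold per dataset: factor, mode, fold,
#' auroc, accuracy, sensitivity, specificity, ppv, npv; six significant
#' digits) and `summary.json` with per-dataset means and, where both
#' division manners of one factor were run, the exact rank-sum p-values
#' between them.
#'
#' @param runs Named list of `eus_cv` objects (names like
#'   `"eda_balanced"`).
#' @param dir Output directory.
#' @return Invisibly, the results data frame.
#' @export
write_results <- function(runs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list(); summ <- list()
  for (nm in names(runs)) {
    cv <- runs[[nm]]
    s <- summary(cv)
    pf <- s$per_fold
    rows[[nm]] <- data.frame(factor = cv$factor, mode = cv$mode, pf)
    summ[[nm]] <- list(factor = cv$factor, mode = cv$mode,
                       mean = as.list(signif(s$mean$mean, 6)))
  }
  res <- do.call(rbind, rows)
  num <- vapply(res, is.numeric, logical(1))
  res[num] <- lapply(res[num], function(x) signif(x, 6))
  utils::write.csv(res, file.path(dir, "results.csv"), row.names = FALSE,
                   quote = FALSE)
  factors <- unique(vapply(runs, `[[`, character(1), "factor"))
  comparisons <- list()
  for (f in factors) {
    o <- runs[[paste0(f, "_ordered")]]; b <- runs[[paste0(f, "_balanced")]]
    if (!is.null(o) && !is.null(b))
      comparisons[[f]] <- as.list(signif(compare_modes(o, b)$p_values, 6))
  }
  jsonlite::write_json(list(datasets = summ,
                            ordered_vs_balanced_p = comparisons),
                       file.path(dir, "summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(res)
}
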