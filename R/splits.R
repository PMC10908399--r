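#' Split factors
#'
#' The five patient-ordering factors: `chr` (session chronology), `age`,
#' `bmi`, `sai` (self-reported alcohol intake, g ethanol/day) and `eda`
#' (endoscopists' diagnostic accuracy, fraction of panel raters whose
#' per-patient diagnosis was correct).
#'
#' @format A named list mapping factor name to the metadata column it reads.
#' @export
eus_factors <- list(chr = "session_date", age = "age_years", bmi = "bmi",
                    sai = "alcohol_g_per_day", eda = "eda_score")

factor_key <- function(factor) {
  factor <- tolower(factor)
  if (!factor %in% names(eus_factors))
    stop(sprintf("unknown factor '%s' (use one of %s)", factor,
                 paste(names(eus_factors), collapse = ", ")), call. = FALSE)
  factor
}

#' Order patients by a clinical factor
#'
#' Patients are ranked by the factor value in ascending order; ties are
#' broken by patient id (lexicographic), so the ranking is a deterministic
#' total order.
#'
#' @param cohort An `eus_cohort` or a metadata data frame (as from
#'   [as.data.frame.eus_cohort()]).
#' @param factor One of `"chr"`, `"age"`, `"bmi"`, `"sai"`, `"eda"`.
#' @return Character vector of patient ids, ranked.
#' @export
order_patients <- function(cohort, factor) {
  meta <- if (inherits(cohort, "eus_cohort")) as.data.frame(cohort) else cohort
  factor <- factor_key(factor)
  col <- eus_factors[[factor]]
  if (!col %in% names(meta))
    stop(sprintf("metadata lacks column '%s' for factor '%s'", col, factor),
         call. = FALSE)
  vals <- meta[[col]]
  if (anyNA(vals))
    stop(sprintf("factor '%s' missing for patient(s) %s", factor,
                 paste(meta$patient_id[is.na(vals)], collapse = ", ")),
         call. = FALSE)
  meta$patient_id[order(vals, meta$patient_id)]
}

#' Divide ranked patients into k groups
#'
#' Two division manners over a factor-ranked patient list:
#' \describe{
#'   \item{ordered}{k contiguous blocks of the ranking, concentrating
#'     similar factor values within groups; the first `n %% k` blocks take
#'     the remainder patients.}
#'   \item{balanced}{round-robin stride assignment (rank r, 0-based, goes
#'     to group `r %% k`), spreading factor values evenly across groups.}
#' }
#' Group sizes differ by at most one in both manners.
#'
#' @param ranked Character vector of patient ids, ranked by a factor (see
#'   [order_patients()]).
#' @param k Number of groups (default 5).
#' @param mode `"ordered"` or `"balanced"`.
#' @param factor Optional factor name recorded in the result.
#' @return An object of class `eus_division`: list with `assignment`
#'   (named integer vector, groups 1..k), `ranked`, `k`, `mode`, `factor`.
#' @export
divide_groups <- function(ranked, k = 5, mode = c("ordered", "balanced"),
                          factor = NA_character_) {
  mode <- match.arg(mode)
  n <- length(ranked)
  if (n < k) stop(sprintf("cannot divide %d patients into %d groups", n, k),
                  call. = FALSE)
  if (anyDuplicated(ranked)) stop("duplicate patient ids", call. = FALSE)
  group <- if (mode == "ordered") {
    sizes <- rep(n %/% k, k) + (seq_len(k) <= n %% k)
    rep(seq_len(k), sizes)
  } else {
    ((seq_len(n) - 1L) %% k) + 1L
  }
  structure(list(assignment = stats::setNames(as.integer(group), ranked),
                 ranked = ranked, k = as.integer(k), mode = mode,
                 factor = factor),
            class = "eus_division")
}

#' @export
print.eus_division <- function(x, ...) {
  cat(sprintf("Patient group division: %d patients, k = %d, mode = %s, factor = %s\n",
              length(x$assignment), x$k, x$mode, x$factor))
  print(table(group = x$assignment))
  invisible(x)
}

#' Enumerate test/validation role allotments
#'
#' With k patient groups, every ordered pair (test group, validation
#' group), test != validation, is one role allotment; the remaining k - 2
#' groups train. For k = 5 this yields the 20 allotments of the 5-fold
#' framework: each test group is paired with its 4 possible validation
#' rotations.
#'
#' @param k Number of groups; must be at least 3 so a training group
#'   remains.
#' @return List of `k * (k - 1)` allotments in test-major order, each a
#'   list with `test`, `validation` and `training` (integer group indices).
#' @export
enumerate_allotments <- function(k = 5) {
  if (k < 3) stop("k must be >= 3 so that a training group remains",
                  call. = FALSE)
  out <- vector("list", k * (k - 1L))
  i <- 0L
  for (test in seq_len(k)) for (val in seq_len(k)) {
    if (val == test) next
    i <- i + 1L
    out[[i]] <- list(test = test, validation = val,
                     training = setdiff(seq_len(k), c(test, val)))
  }
  out
}

#' Audit image batches for patient-level information leakage
#'
#' The framework splits patients, never images: under one role allotment a
#' patient's images may appear under exactly one of the training,
#' validation and test roles. The audit fails if and only if some patient
#' contributed images to more than one role; role assignments inconsistent
#' with the division are additionally reported.
#'
#' @param division An [divide_groups()] result.
#' @param allotment One element of [enumerate_allotments()].
#' @param batches Data frame with columns `patient_id` and `role`
#'   (`"training"`, `"validation"` or `"test"`), one row per image (or per
#'   patient-role pair).
#' @return A list of class `eus_leakage_report`: `pass` (logical),
#'   `offenders` (patients in more than one role), `mismatches` (patients
#'   whose role disagrees with their group's role).
#' @export
check_leakage <- function(division, allotment, batches) {
  if (nrow(batches) == 0L)
    return(structure(list(pass = TRUE, offenders = character(0),
                          mismatches = character(0)),
                     class = "eus_leakage_report"))
  stopifnot(all(c("patient_id", "role") %in% names(batches)))
  roles_by_patient <- tapply(batches$role, batches$patient_id,
                             function(r) unique(r))
  offenders <- names(roles_by_patient)[lengths(roles_by_patient) > 1L]
  role_of_group <- function(g) {
    if (g == allotment$test) "test"
    else if (g == allotment$validation) "validation"
    else "training"
  }
  expected <- vapply(division$assignment[names(roles_by_patient)],
                     role_of_group, character(1))
  actual_one <- vapply(roles_by_patient, `[`, character(1), 1L)
  mismatches <- names(roles_by_patient)[
    lengths(roles_by_patient) == 1L & actual_one != expected]
  structure(list(pass = length(offenders) == 0L,
                 offenders = offenders,
                 mismatches = mismatches),
            class = "eus_leakage_report")
}

#' @export
print.eus_leakage_report <- function(x, ...) {
  cat(sprintf("Leakage audit: %s\n", if (x$pass) "PASS" else "FAIL"))
  if (length(x$offenders))
    cat("  patients in more than one role:",
        paste(x$offenders, collapse = ", "), "\n")
  if (length(x$mismatches))
    cat("  role inconsistent with division:",
        paste(x$mismatches, collapse = ", "), "\n")
  invisible(x)
}

# Patients of a division belonging to the given groups.
patients_in_groups <- function(cohort, division, groups) {
  ids <- names(division$assignment)[division$assignment %in% groups]
  keep <- vapply(cohort$patients, function(p) p$patient_id %in% ids,
                 logical(1))
  cohort$patients[keep]
}
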