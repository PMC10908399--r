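#' Specification of a synthetic EUS cohort
#'
#' Describes the statistical structure of a synthetic endoscopic-ultrasound
#' cohort: two patient classes (label 1 = PDAC-like, label 0 = AIP-like),
#' one to a few video clips per patient, speckle-textured grayscale frames
#' with one elliptical lesion per patient whose interior texture differs
#' between the classes by a controllable effect size, clinical covariates,
#' and a simulated endoscopist rater panel.
#'
#' `effect_size` is the class separation of the latent lesion-contrast
#' parameter in units of its per-patient standard deviation (a Cohen's d):
#' 0 makes the classes indistinguishable, 2 gives a strong, learnable
#' signal.
#'
#' @param n_positive Number of PDAC-like (label 1) patients.
#' @param n_negative Number of AIP-like (label 0) patients.
#' @param videos_per_patient Integer range `c(lo, hi)` of videos per patient.
#' @param frames_per_video Integer range `c(lo, hi)` of frames per video;
#'   the lower bound must be at least 3 because a quasi-RGB image needs
#'   three distinct frames.
#' @param frame_height,frame_width Raw (pre-crop) frame dimensions in
#'   pixels; must accommodate the crop box used downstream.
#' @param effect_size Nonnegative real; standardized class separation of
#'   the lesion texture parameters.
#' @param covariate_params Named list of covariate distributions; see
#'   Details. Defaults give realistic ranges for age (years), BMI (kg/m2),
#'   daily ethanol intake (g/day) and session chronology.
#' @param n_experts,n_novices Rater counts of the simulated panel.
#' @param confound Optional list `list(factor =, strength =)` correlating
#'   one covariate (`"age"`, `"bmi"` or `"alcohol"`) with the class label,
#'   for studying ordered-versus-balanced division behaviour. `strength`
#'   is the standardized mean shift added to the positive class.
#' @param seed Integer seed; the generated cohort is a pure function of
#'   the spec (including this seed).
#'
#' @details `covariate_params` elements: `age = c(mean, sd, min, max)`,
#'   `bmi = c(mean, sd, min, max)`,
#'   `alcohol = c(p_light, p_moderate, p_heavy)` (mixture weights of the
#'   light/moderate/heavy drinking strata).
#'
#' @return An object of class `eus_cohort_spec`.
#' @seealso [generate_cohort()]
#' @export
cohort_spec <- function(n_positive = 61, n_negative = 24,
                        videos_per_patient = c(1L, 3L),
                        frames_per_video = c(100L, 300L),
                        frame_height = 540, frame_width = 500,
                        effect_size = 1,
                        covariate_params = list(),
                        n_experts = 4, n_novices = 3,
                        confound = NULL,
                        seed = 1L) {
  if (!is.numeric(n_positive) || length(n_positive) != 1L || n_positive < 1)
    abort_field("n_positive", "must be a count >= 1")
  if (!is.numeric(n_negative) || length(n_negative) != 1L || n_negative < 1)
    abort_field("n_negative", "must be a count >= 1")
  check_range_pair(videos_per_patient, "videos_per_patient", lower_min = 1)
  check_range_pair(frames_per_video, "frames_per_video", lower_min = 3)
  if (!is.numeric(frame_height) || frame_height < 32)
    abort_field("frame_height", "must be at least 32 pixels")
  if (!is.numeric(frame_width) || frame_width < 32)
    abort_field("frame_width", "must be at least 32 pixels")
  if (!is.numeric(effect_size) || length(effect_size) != 1L || effect_size < 0)
    abort_field("effect_size", "must be a nonnegative real")
  if (n_experts < 0 || n_novices < 0)
    abort_field("n_experts", "rater counts must be nonnegative")
  defaults <- list(age = c(mean = 70, sd = 10, min = 40, max = 85),
                   bmi = c(mean = 22, sd = 3, min = 15, max = 38),
                   alcohol = c(p_light = 0.65, p_moderate = 0.27,
                               p_heavy = 0.08))
  unknown <- setdiff(names(covariate_params), names(defaults))
  if (length(unknown))
    abort_field("covariate_params", paste("unknown entries:",
                                          paste(unknown, collapse = ", ")))
  cov <- utils::modifyList(defaults, covariate_params)
  if (!is.null(confound)) {
    if (!is.list(confound) || is.null(confound$factor) ||
        !confound$factor %in% c("age", "bmi", "alcohol"))
      abort_field("confound", "must be list(factor = 'age'|'bmi'|'alcohol', strength = <real>)")
    if (is.null(confound$strength)) confound$strength <- 1
  }
  structure(list(n_positive = as.integer(n_positive),
                 n_negative = as.integer(n_negative),
                 videos_per_patient = as.integer(videos_per_patient),
                 frames_per_video = as.integer(frames_per_video),
                 frame_height = as.integer(frame_height),
                 frame_width = as.integer(frame_width),
                 effect_size = effect_size,
                 covariate_params = cov,
                 n_experts = as.integer(n_experts),
                 n_novices = as.integer(n_novices),
                 confound = confound,
                 seed = as.integer(seed)),
            class = "eus_cohort_spec")
}

# Fixed constants of the lesion texture model (see the methods vignette).
# tau: per-patient jitter sd of the lesion contrast parameter; effect_size
# is expressed in units of tau. mu0: lesion contrast of the negative class
# (mildly hypoechoic relative to background).
.texture_model <- list(tau = 0.04, mu0 = -0.06,
                       log_sigma0 = log(0.025), log_sigma_slope = 0.2,
                       log_sigma_sd = 0.1, diag_scale = 50)

#' Generate a synthetic EUS cohort
#'
#' Draws a full cohort of patients from a [cohort_spec()]: labels, clinical
#' covariates, per-patient lesion texture parameters, and grayscale video
#' frames. Frames carry a smooth low-frequency background, one elliptical
#' lesion whose interior mean and heterogeneity are class-dependent,
#' multiplicative Rayleigh speckle, a dark bottom band (where ultrasound
#' waves do not reach) and bright corner annotation marks; the latter two
#' exist so the crop stage has something real to remove. Consecutive frames
#' of one video are correlated through a small random-walk translation of
#' the underlying field with fresh speckle per frame.
#'
#' The per-patient latent `diagnosability` in `[0, 1]` is a logistic
#' transform of the patient's realized lesion-contrast separation from the
#' class midpoint; it drives the simulated rater panel of
#' [simulate_endoscopists()]. The same spec (including its seed) always
#' reproduces the cohort bit for bit.
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `eus_cohort`: a list with elements
#'   `patients` (list of patient records) and `spec`. Each patient record
#'   holds `patient_id`, `label`, covariates, `diagnosability`, the ground
#'   truth `truth` (lesion parameters), and `videos`, a named list of
#'   integer frame matrices with values in 0..255.
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "eus_cohort_spec"))
    stop("'spec' must be created by cohort_spec()", call. = FALSE)
  with_seed(spec$seed, {
    n <- spec$n_positive + spec$n_negative
    ids <- sprintf("P%03d", seq_len(n))
    labels <- sample(rep(c(1L, 0L), c(spec$n_positive, spec$n_negative)))

    cov <- spec$covariate_params
    age <- round(pmin(pmax(stats::rnorm(n, cov$age["mean"], cov$age["sd"]),
                           cov$age["min"]), cov$age["max"]))
    bmi <- round(pmin(pmax(stats::rnorm(n, cov$bmi["mean"], cov$bmi["sd"]),
                           cov$bmi["min"]), cov$bmi["max"]), 1)
    stratum <- sample(c("light", "moderate", "heavy"), n, replace = TRUE,
                      prob = cov$alcohol)
    alcohol <- numeric(n)
    alcohol[stratum == "light"] <- round(stats::runif(sum(stratum == "light"), 0, 20), 1)
    alcohol[stratum == "moderate"] <- round(stats::runif(sum(stratum == "moderate"), 20, 60), 1)
    alcohol[stratum == "heavy"] <- round(60 + stats::rexp(sum(stratum == "heavy"), 1 / 30), 1)
    if (!is.null(spec$confound)) {
      sh <- spec$confound$strength
      pos <- labels == 1L
      if (spec$confound$factor == "age")
        age[pos] <- round(pmin(age[pos] + sh * cov$age["sd"], cov$age["max"]))
      if (spec$confound$factor == "bmi")
        bmi[pos] <- round(pmin(bmi[pos] + sh * cov$bmi["sd"], cov$bmi["max"]), 1)
      if (spec$confound$factor == "alcohol")
        alcohol[pos] <- round(alcohol[pos] + sh * 15, 1)
    }
    alcohol_category <- alcohol_category(alcohol)
    session_date <- sample(seq_len(n))

    tm <- .texture_model
    mu <- c(tm$mu0, tm$mu0 - spec$effect_size * tm$tau)  # by label 0/1
    mu_mid <- mean(mu)
    patients <- vector("list", n)
    for (i in seq_len(n)) {
      lab <- labels[i]
      contrast <- stats::rnorm(1, mu[lab + 1L], tm$tau)
      sigma <- exp(stats::rnorm(1, tm$log_sigma0 +
                                  tm$log_sigma_slope * spec$effect_size * lab,
                                tm$log_sigma_sd))
      sep <- (2 * lab - 1) * (mu_mid - contrast)
      diagnosability <- stats::plogis(tm$diag_scale * sep)
      geometry <- list(cy = stats::runif(1, 0.38, 0.52),
                       cx = stats::runif(1, 0.42, 0.58),
                       ry = stats::runif(1, 0.12, 0.22),
                       rx = stats::runif(1, 0.14, 0.26),
                       theta = stats::runif(1, 0, pi))
      n_videos <- runif_int(1, spec$videos_per_patient[1],
                            spec$videos_per_patient[2])
      videos <- vector("list", n_videos)
      names(videos) <- sprintf("V%d", seq_len(n_videos))
      for (v in seq_len(n_videos)) {
        n_frames <- runif_int(1, spec$frames_per_video[1],
                              spec$frames_per_video[2])
        videos[[v]] <- render_video(spec$frame_height, spec$frame_width,
                                    n_frames, contrast, sigma, geometry)
      }
      patients[[i]] <- list(patient_id = ids[i], label = lab,
                            age = age[i], bmi = bmi[i],
                            alcohol_g_per_day = alcohol[i],
                            alcohol_category = alcohol_category[i],
                            session_date = session_date[i],
                            eda_score = NA_real_,
                            diagnosability = diagnosability,
                            truth = list(lesion_contrast = contrast,
                                         lesion_sigma = sigma,
                                         geometry = geometry),
                            videos = videos)
    }
    structure(list(patients = patients, spec = spec), class = "eus_cohort")
  })
}

#' Alcohol intake category
#'
#' Drinking strata by daily ethanol intake: light < 20 g/day, moderate
#' 20-60 g/day, heavy >= 60 g/day.
#'
#' @param g_per_day Numeric vector of daily ethanol intake in grams.
#' @return Character vector in `c("light", "moderate", "heavy")`.
#' @export
alcohol_category <- function(g_per_day) {
  ifelse(g_per_day < 20, "light", ifelse(g_per_day < 60, "moderate", "heavy"))
}

# Render one video: a smooth background field with an elliptical lesion,
# translated by a bounded random walk across frames, with fresh
# multiplicative Rayleigh speckle, a dark bottom band and corner marks.
render_video <- function(h, w, n_frames, contrast, sigma, geom,
                         margin = 4L) {
  H <- h + 2L * margin; W <- w + 2L * margin
  y <- seq_len(H); x <- seq_len(W)
  fy <- stats::runif(1, 1, 3); fx <- stats::runif(1, 1, 3)
  py <- stats::runif(1, 0, 2 * pi); px <- stats::runif(1, 0, 2 * pi)
  # centered low-frequency field: constant global mean across videos, as
  # after gain normalization, so class signal lives in lesion texture and
  # not in global brightness
  cy_ <- cos(2 * pi * fy * y / H + py); cx_ <- cos(2 * pi * fx * x / W + px)
  bg <- 0.42 + 0.08 * (outer(cy_, cx_) - mean(cy_) * mean(cx_))
  # elliptical lesion mask in the field's coordinates
  cy <- geom$cy * H; cx <- geom$cx * W
  ry <- geom$ry * H; rx <- geom$rx * W
  ct <- cos(geom$theta); st <- sin(geom$theta)
  dy <- outer(y - cy, rep(1, W)); dx <- outer(rep(1, H), x - cx)
  u <- (dy * ct + dx * st) / ry
  v <- (-dy * st + dx * ct) / rx
  mask <- (u * u + v * v) <= 1
  field <- bg
  field[mask] <- field[mask] + contrast +
    stats::rnorm(sum(mask), 0, sigma)

  band <- max(4L, round(0.08 * h))
  mark <- max(3L, round(0.012 * w))
  frames <- vector("list", n_frames)
  off_y <- margin; off_x <- margin
  rayleigh_sigma <- sqrt(2 / pi)  # unit-mean multiplicative speckle
  for (j in seq_len(n_frames)) {
    if (j > 1L) {
      off_y <- min(max(off_y + runif_int(1, -2, 2), 0L), 2L * margin)
      off_x <- min(max(off_x + runif_int(1, -2, 2), 0L), 2L * margin)
    }
    fr <- field[(off_y + 1L):(off_y + h), (off_x + 1L):(off_x + w)]
    speckle <- rayleigh_sigma * sqrt(-2 * log(stats::runif(h * w)))
    fr <- fr * speckle
    fr[(h - band + 1L):h, ] <- stats::runif(band * w, 0, 0.03)
    fr[1:mark, c(1:mark, (w - mark + 1L):w)] <- 1
    fr <- pmin(pmax(fr, 0), 1)
    fr <- matrix(as.integer(round(255 * fr)), h, w)
    frames[[j]] <- fr
  }
  frames
}

#' Simulate an endoscopist rater panel
#'
#' Each simulated rater watches every patient's images and emits one binary
#' diagnosis per patient. A rater's probability of a correct call is
#' `0.5 + skill * (diagnosability - 0.5)`, so `skill = 1` reproduces the
#' patient's latent diagnosability exactly and `skill = 0` is guessing;
#' experts are at least as skilled as novices. The per-patient endoscopist
#' diagnostic accuracy (EDA) score -- the fraction of raters whose call was
#' correct -- is written back to each patient record and later serves as
#' the EDA split factor.
#'
#' @param cohort An `eus_cohort`.
#' @param n_experts,n_novices Rater counts; default from the cohort spec.
#' @param skill Named numeric `c(expert =, novice =)` in `[0, 1]`.
#' @param seed Integer seed (default derived from the cohort spec seed).
#' @return The cohort with `eda_score` filled in and an attribute
#'   `"panel"`: a list with the rater-by-patient `diagnoses` matrix,
#'   `correct` matrix, `rater_type`, and patient labels.
#' @export
simulate_endoscopists <- function(cohort, n_experts = NULL, n_novices = NULL,
                                  skill = c(expert = 0.95, novice = 0.65),
                                  seed = NULL) {
  stopifnot(inherits(cohort, "eus_cohort"))
  if (length(cohort$patients) == 0L)
    stop("cohort is empty", call. = FALSE)
  if (is.null(n_experts)) n_experts <- cohort$spec$n_experts
  if (is.null(n_novices)) n_novices <- cohort$spec$n_novices
  n_raters <- n_experts + n_novices
  if (n_raters == 0L) stop("n_experts + n_novices must be > 0", call. = FALSE)
  if (any(skill < 0) || any(skill > 1) ||
      !all(c("expert", "novice") %in% names(skill)))
    abort_field("skill", "must be named probabilities for expert and novice")
  if (skill["expert"] < skill["novice"])
    abort_field("skill", "experts must be at least as skilled as novices")
  if (is.null(seed)) seed <- derive_seed(cohort$spec$seed, "endoscopists")
  diag_p <- vapply(cohort$patients, `[[`, numeric(1), "diagnosability")
  labels <- vapply(cohort$patients, `[[`, integer(1), "label")
  ids <- vapply(cohort$patients, `[[`, character(1), "patient_id")
  rater_type <- rep(c("expert", "novice"), c(n_experts, n_novices))
  with_seed(seed, {
    p_correct <- outer(skill[rater_type], diag_p - 0.5) + 0.5
    correct <- matrix(stats::runif(length(p_correct)) < p_correct,
                      nrow = n_raters,
                      dimnames = list(sprintf("R%d", seq_len(n_raters)), ids))
    diagnoses <- ifelse(correct, rep(labels, each = n_raters),
                        1L - rep(labels, each = n_raters))
    eda <- colMeans(correct)
    for (i in seq_along(cohort$patients))
      cohort$patients[[i]]$eda_score <- eda[i]
    attr(cohort, "panel") <- list(diagnoses = diagnoses, correct = correct,
                                  rater_type = rater_type, labels = labels,
                                  eda_score = eda)
    cohort
  })
}

#' Per-rater diagnostic performance of the simulated panel
#'
#' Computes accuracy, sensitivity, specificity, PPV and NPV for each rater
#' of the panel attached by [simulate_endoscopists()], averaged over all
#' raters, the experts only, or the novices only (each rater's metrics are
#' computed on their own per-patient diagnoses and then averaged).
#'
#' @param cohort A cohort returned by [simulate_endoscopists()].
#' @param raters One of `"all"`, `"experts"`, `"novices"`.
#' @return Named numeric vector of mean metrics.
#' @export
panel_metrics <- function(cohort, raters = c("all", "experts", "novices")) {
  raters <- match.arg(raters)
  panel <- attr(cohort, "panel")
  if (is.null(panel)) stop("cohort has no simulated panel; run simulate_endoscopists() first",
                           call. = FALSE)
  keep <- switch(raters, all = rep(TRUE, nrow(panel$diagnoses)),
                 experts = panel$rater_type == "expert",
                 novices = panel$rater_type == "novice")
  per_rater <- apply(panel$diagnoses[keep, , drop = FALSE], 1, function(d) {
    m <- confusion_metrics(d, panel$labels)
    c(accuracy = m$accuracy, sensitivity = m$sensitivity,
      specificity = m$specificity, ppv = m$ppv, npv = m$npv)
  })
  rowMeans(per_rater, na.rm = TRUE)
}

#' @export
print.eus_cohort <- function(x, ...) {
  labels <- vapply(x$patients, `[[`, integer(1), "label")
  n_frames <- sum(vapply(x$patients, function(p)
    sum(vapply(p$videos, length, integer(1))), numeric(1)))
  cat(sprintf("Synthetic EUS cohort: %d patients (%d PDAC-like, %d AIP-like)\n",
              length(x$patients), sum(labels == 1L), sum(labels == 0L)))
  cat(sprintf("  frames: %d total, %d x %d px raw; effect size %.2f; seed %d\n",
              n_frames, x$spec$frame_height, x$spec$frame_width,
              x$spec$effect_size, x$spec$seed))
  invisible(x)
}

#' Cohort metadata as a data frame
#'
#' @param x An `eus_cohort`.
#' @param row.names,optional,... Passed on conventionally; unused.
#' @return A data frame with one row per patient: `patient_id`, `label`,
#'   `age_years`, `bmi`, `alcohol_g_per_day`, `alcohol_category`,
#'   `session_date`, `eda_score`, `diagnosability`.
#' @export
as.data.frame.eus_cohort <- function(x, row.names = NULL, optional = FALSE, ...) {
  p <- x$patients
  data.frame(patient_id = vapply(p, `[[`, character(1), "patient_id"),
             label = vapply(p, `[[`, integer(1), "label"),
             age_years = vapply(p, `[[`, numeric(1), "age"),
             bmi = vapply(p, `[[`, numeric(1), "bmi"),
             alcohol_g_per_day = vapply(p, `[[`, numeric(1), "alcohol_g_per_day"),
             alcohol_category = vapply(p, `[[`, character(1), "alcohol_category"),
             session_date = vapply(p, `[[`, numeric(1), "session_date"),
             eda_score = vapply(p, `[[`, numeric(1), "eda_score"),
             diagnosability = vapply(p, `[[`, numeric(1), "diagnosability"),
             stringsAsFactors = FALSE)
}
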