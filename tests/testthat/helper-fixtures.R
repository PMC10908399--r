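# Shared fixtures: small synthetic cohorts, memoised per test session.

.fixture_cache <- new.env(parent = emptyenv())

# A small cropped cohort with a simulated rater panel.
test_cohort <- function(n_pos = 12, n_neg = 8, effect = 2, seed = 42,
                        frames = c(5, 8), videos = c(1, 2),
                        h = 120, w = 110) {
  key <- paste(n_pos, n_neg, effect, seed, frames[1], frames[2],
               videos[1], videos[2], h, w, sep = "_")
  if (!exists(key, .fixture_cache)) {
    spec <- cohort_spec(n_positive = n_pos, n_negative = n_neg,
                        videos_per_patient = videos,
                        frames_per_video = frames,
                        frame_height = h, frame_width = w,
                        effect_size = effect, seed = seed)
    co <- preprocess_cohort(simulate_endoscopists(generate_cohort(spec)))
    assign(key, co, .fixture_cache)
  }
  get(key, .fixture_cache)
}

# Fast training configuration for driver-level tests.
fast_config <- function(target = 64) {
  train_config(epochs = 3, n_val_per_class = 10,
               sampling = sampling_config(n_per_epoch = 30,
                                          n_test_per_patient = 5,
                                          target = target))
}

# Memoised small cross-validation run shared by several tests.
test_cv_run <- function() {
  if (!exists("cv_run", .fixture_cache)) {
    co <- test_cohort()
    cv <- eus_crossval(co, factor = "chr", mode = "balanced",
                       config = fast_config(), seed = 9)
    assign("cv_run", cv, .fixture_cache)
  }
  get("cv_run", .fixture_cache)
}

# Hand-built constant-score head: always predicts plogis(bias).
constant_head <- function(p, output_dim = 16) {
  structure(list(weights = numeric(output_dim), bias = stats::qlogis(p),
                 best_epoch = 1L, best_val_auroc = NA_real_,
                 log = data.frame(), extractor_name = "constant",
                 output_dim = output_dim, config = NULL,
                 patients_seen = list()),
            class = "eus_head")
}

# Exhaustive pairwise-comparison AUROC oracle.
pairwise_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}
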