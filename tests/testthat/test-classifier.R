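test_that("random-projection extractor matches a direct matrix-product oracle", {
  ex <- random_projection_extractor(output_dim = 8, input_size = 32, seed = 2)
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  feats <- extract_features(ex, list(img, img))
  # independent oracle: explicit per-channel matrix multiply
  oracle <- ex$weights[[1]] %*% as.vector(img[, , 1]) +
    ex$weights[[2]] %*% as.vector(img[, , 2]) +
    ex$weights[[3]] %*% as.vector(img[, , 3])
  expect_equal(feats[1, ], drop(oracle))
  expect_identical(feats[1, ], feats[2, ])            # duplicate image rows
  empty <- extract_features(ex, list())
  expect_identical(dim(empty), c(0L, 8L))
  expect_error(extract_features(ex, list(array(0, c(16, 16, 3)))),
               "expected 32 x 32 x 3")
})

test_that("per-frame feature cache reproduces the direct compose-extract path", {
  co <- test_cohort()
  ex <- random_projection_extractor(output_dim = 16, input_size = 48,
                                    seed = 3)
  cache <- euscv:::build_frame_feature_cache(ex, co$patients, 48)
  cfg <- sampling_config(n_per_epoch = 20, n_test_per_patient = 5,
                         target = 48)
  plan <- sample_epoch(co$patients, cfg, seed = 5, materialize = FALSE)
  f_cached <- euscv:::plan_features(ex, co$patients, plan, cfg, cache)
  f_direct <- euscv:::plan_features(ex, co$patients, plan, cfg, NULL)
  expect_equal(f_cached, f_direct, tolerance = 1e-12)
})

test_that("SGD head separates linearly separable classes within 20 epochs", {
  # frames with opposite vertical gradients per class: features are
  # linearly separable with margin
  mk <- function(id, label, value) {
    half <- rbind(matrix(as.integer(value), 20, 40),
                  matrix(as.integer(250 - value), 20, 40))
    if (label == 1L) half <- half[40:1, ]
    frames <- replicate(6, half, simplify = FALSE)
    list(patient_id = id, label = label, videos = list(V1 = frames))
  }
  train_p <- c(lapply(1:3, function(i) mk(sprintf("a%d", i), 0L, 60 + i)),
               lapply(1:3, function(i) mk(sprintf("b%d", i), 1L, 60 + i)))
  val_p <- list(mk("v0", 0L, 65), mk("v1", 1L, 65))
  ex <- random_projection_extractor(output_dim = 8, input_size = 32,
                                    seed = 4)
  cfg <- train_config(epochs = 20, n_val_per_class = 5,
                      sampling = sampling_config(n_per_epoch = 40,
                                                 n_test_per_patient = 5,
                                                 target = 32))
  head <- train_head(ex, train_p, val_p, cfg)
  plan <- sample_epoch(train_p, cfg$sampling, seed = 77,
                       materialize = FALSE)
  X <- euscv:::plan_features(ex, train_p, plan, cfg$sampling, NULL)
  # end-of-training parameters reach separation; the stored checkpoint is
  # the earliest best-validation epoch, which may precede convergence
  scores_final <- plogis(drop(X %*% head$final$weights) + head$final$bias)
  acc <- mean((scores_final >= 0.5) == plan$label)
  expect_gte(acc, 0.95)
  expect_equal(head$best_val_auroc, 1)
  expect_true(all(diff(head$log$train_loss) < 0))
})

test_that("checkpoint stores the earliest best-validation-AUROC epoch", {
  expect_identical(euscv:::select_best_epoch(c(0.5, 0.7, 0.7, 0.6)), 2L)
  expect_identical(euscv:::select_best_epoch(c(0.9, 0.2)), 1L)
  cv <- test_cv_run()
  for (h in cv$heads) {
    expect_equal(h$best_val_auroc, max(h$log$val_auroc))
    expect_identical(h$best_epoch,
                     which.max(h$log$val_auroc))
    expect_identical(nrow(h$log), h$config$epochs)
  }
})

test_that("the extractor stays frozen through training", {
  ex <- random_projection_extractor(output_dim = 8, input_size = 48,
                                    seed = 6)
  w_before <- lapply(ex$weights, identity)
  co <- test_cohort()
  cfg <- fast_config(target = 48)
  invisible(train_head(ex, co$patients[1:10], co$patients[11:14], cfg))
  expect_identical(ex$weights, w_before)
  img <- array(0.5, c(48, 48, 3))
  expect_identical(extract_features(ex, list(img)),
                   extract_features(ex, list(img)))
})

test_that("median-of-4 ensemble follows the even-count median rule", {
  expect_equal(ensemble_median(c(0.1, 0.2, 0.8, 0.9)), 0.5)
  expect_equal(ensemble_median(c(0.7, 0.7, 0.7, 0.7)), 0.7)
  for (perm in list(c(1, 2, 3, 4), c(4, 3, 2, 1), c(2, 4, 1, 3)))
    expect_equal(ensemble_median(c(0.1, 0.4, 0.6, 1.0)[perm]), 0.5)
  # bounded by members; equals the middle pair mean under 3-of-4 agreement
  expect_equal(ensemble_median(c(0.2, 0.2, 0.2, 0.9)), 0.2)
  expect_error(ensemble_median(c(0.1, 0.2, 0.3)), "exactly 4")
  expect_error(ensemble_median(c(0.1, 0.2, 0.3, 1.2)), "\\[0, 1\\]")
})

test_that("patient prediction propagates constant heads exactly", {
  co <- test_cohort()
  p <- co$patients[[1]]
  ex <- random_projection_extractor(output_dim = 16, input_size = 32,
                                    seed = 1)
  cfg <- sampling_config(n_per_epoch = 10, n_test_per_patient = 7,
                         target = 32)
  heads_c <- lapply(rep(0.3, 4), constant_head)
  pred <- predict_patient(heads_c, ex, p, cfg, seed = 5)
  expect_equal(pred$score, 0.3, tolerance = 1e-9)
  heads_01 <- lapply(c(1e-9, 1e-9, 1 - 1e-9, 1 - 1e-9), constant_head)
  pred01 <- predict_patient(heads_01, ex, p, cfg, seed = 5)
  expect_equal(pred01$score, 0.5, tolerance = 1e-6)
  expect_identical(pred$plan,
                   predict_patient(heads_c, ex, p, cfg, seed = 5)$plan)
  expect_error(predict_patient(heads_c[1:3], ex, p, cfg, seed = 1),
               "4 heads")
})

test_that("cross-validation runs 20 sessions, audits leakage, is deterministic", {
  cv <- test_cv_run()
  expect_identical(cv$n_sessions, 20L)
  expect_length(cv$heads, 20L)
  expect_length(cv$audits, 20L)
  expect_true(all(vapply(cv$audits, `[[`, logical(1), "pass")))
  # every patient scored exactly once, in their division's test group
  expect_setequal(cv$scores$patient_id, names(cv$division$assignment))
  expect_identical(unname(cv$division$assignment[cv$scores$patient_id]),
                   cv$scores$test_group)
  expect_true(all(cv$scores$score >= 0 & cv$scores$score <= 1))
  cv2 <- eus_crossval(test_cohort(), factor = "chr", mode = "balanced",
                      config = fast_config(), seed = 9)
  expect_identical(cv$scores, cv2$scores)
  s <- summary(cv)
  expect_identical(nrow(s$per_fold), 5L)
})
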