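test_that("cropping returns the exact box and rejects out-of-bounds boxes", {
  raw <- matrix(seq_len(600 * 700) %% 256L, 600, 700)
  out <- crop_frame(raw, crop_box(top = 10, left = 20))
  expect_identical(dim(out), c(489L, 465L))
  expect_identical(out[1, 1], raw[10, 20])
  expect_identical(out[489, 465], raw[498, 484])
  # identity crop
  expect_identical(crop_frame(raw, crop_box(1, 1, 600, 700)), raw)
  # no silent clamping
  expect_error(crop_frame(raw, crop_box(1, 300, 489, 465)), "exceeds")
})

test_that("bilinear resize is deterministic with the expected invariants", {
  img <- matrix(runif(224 * 224), 224, 224)
  expect_identical(resize_image(img, 224), img)       # identity, bit-equal
  const <- matrix(0.37, 489, 465)
  out <- resize_image(const, 224)
  expect_lt(max(abs(out - 0.37)), 1 / 255)            # constant preserved
  # exact 2x downscale equals 2x2 block averaging (independent oracle)
  sq <- matrix(0, 448, 448); sq[129:320, 129:320] <- 1
  blocks <- 0.25 * (sq[seq(1, 447, 2), seq(1, 447, 2)] +
                    sq[seq(2, 448, 2), seq(1, 447, 2)] +
                    sq[seq(1, 447, 2), seq(2, 448, 2)] +
                    sq[seq(2, 448, 2), seq(2, 448, 2)])
  expect_lt(max(abs(resize_image(sq, 224) - blocks)), 1e-12)
  expect_error(resize_image(matrix(numeric(0), 0, 0), 224), "empty")
})

test_that("quasi-RGB composition uses three distinct in-order frames of one patient", {
  co <- test_cohort()
  p <- co$patients[[1]]
  q <- compose_quasi_rgb(p, seed = 3, target = 48)
  expect_s3_class(q, "eus_quasi_rgb")
  expect_identical(dim(q$pixels), c(48L, 48L, 3L))
  expect_identical(q$patient_id, p$patient_id)
  expect_true(all(diff(q$frame_index) > 0))           # ascending temporal order
  expect_length(unique(q$video_id), 1L)               # same_video_only default
  # pool of exactly 3 frames: forced selection
  p3 <- p; p3$videos <- list(V1 = p$videos[[1]][1:3])
  q3 <- compose_quasi_rgb(p3, seed = 1, target = 32)
  expect_identical(q3$frame_index, 1:3)
  # identical source frames give identical channels
  pid <- p; pid$videos <- list(V1 = rep(p$videos[[1]][1], 3))
  qid <- compose_quasi_rgb(pid, seed = 1, target = 32)
  expect_identical(qid$pixels[, , 1], qid$pixels[, , 2])
  expect_identical(qid$pixels[, , 2], qid$pixels[, , 3])
  # too few frames: error names the patient
  p2 <- p; p2$videos <- list(V1 = p$videos[[1]][1:2])
  expect_error(compose_quasi_rgb(p2, seed = 1), p$patient_id)
})

test_that("channel order tracks temporal order whatever the draw order", {
  co <- test_cohort()
  p <- co$patients[[2]]
  # many seeded draws: indices always sorted, never duplicated
  for (s in 1:20) {
    q <- compose_quasi_rgb(p, seed = s, target = 32)
    expect_identical(q$frame_index, sort(unique(q$frame_index)))
    expect_length(q$frame_index, 3L)
  }
})

test_that("augmentation: identity when disabled, flip is an involution, seeded", {
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  expect_identical(augment_image(img, NULL, seed = 1), img)
  off <- augment_config(hflip = 0, max_rotate = 0, max_brightness = 0)
  expect_equal(augment_image(img, off, seed = 1), img)
  flip_only <- augment_config(hflip = 1, max_rotate = 0, max_brightness = 0)
  once <- augment_image(img, flip_only, seed = 1)
  expect_false(identical(once, img))
  expect_equal(augment_image(once, flip_only, seed = 2), img)
  full <- augment_config()
  expect_identical(augment_image(img, full, seed = 5),
                   augment_image(img, full, seed = 5))
})

test_that("epoch sampling balances classes and patients as specified", {
  co <- test_cohort()
  cfg <- sampling_config(n_per_epoch = 1000, n_test_per_patient = 5)
  plan <- sample_epoch(co$patients, cfg, seed = 4, materialize = FALSE)
  expect_identical(nrow(plan), 1000L)
  expect_identical(sum(plan$label == 1L), 500L)
  expect_identical(sum(plan$label == 0L), 500L)
  # odd count: the extra image goes to class 1
  cfg999 <- sampling_config(n_per_epoch = 999, n_test_per_patient = 5)
  plan999 <- sample_epoch(co$patients, cfg999, seed = 4, materialize = FALSE)
  expect_identical(sum(plan999$label == 1L), 500L)
  expect_identical(sum(plan999$label == 0L), 499L)
  # round-robin per patient within class: 3 patients, 500 images
  labels <- vapply(co$patients, `[[`, integer(1), "label")
  neg3 <- co$patients[which(labels == 0L)[1:3]]
  pos1 <- co$patients[which(labels == 1L)[1]]
  plan3 <- sample_epoch(c(neg3, pos1), cfg, seed = 1, materialize = FALSE)
  counts <- table(plan3$patient_id[plan3$label == 0L])
  expect_true(all(counts %in% c(166L, 167L)))
  expect_identical(sum(counts), 500L)
  # missing class errors with the class named
  expect_error(sample_epoch(neg3, cfg, seed = 1, materialize = FALSE),
               "class 1")
})

test_that("epoch samples are patient-consistent and reproducible", {
  co <- test_cohort()
  cfg <- sampling_config(n_per_epoch = 60, n_test_per_patient = 5,
                         target = 32)
  for (s in 1:5) {
    plan <- sample_epoch(co$patients, cfg, seed = s, materialize = FALSE)
    expect_true(all(abs(sum(plan$label == 1L) - sum(plan$label == 0L)) <= 1))
    # every image's three frames belong to one patient by construction;
    # frame triples are distinct and temporally ordered
    same_video <- plan$video_1 == plan$video_2 & plan$video_2 == plan$video_3
    expect_true(all(same_video))
    expect_true(all(plan$idx_1 < plan$idx_2 & plan$idx_2 < plan$idx_3))
  }
  expect_identical(sample_epoch(co$patients, cfg, 7, materialize = FALSE),
                   sample_epoch(co$patients, cfg, 7, materialize = FALSE))
  imgs <- sample_epoch(co$patients, cfg, seed = 2)
  expect_length(imgs, 60L)
  expect_identical(attr(imgs, "plan")$patient_id,
                   vapply(imgs, `[[`, character(1), "patient_id"))
})

test_that("test-set sampling yields the configured count, seeded", {
  co <- test_cohort()
  p <- co$patients[[3]]
  cfg <- sampling_config(n_per_epoch = 10, n_test_per_patient = 300)
  plan <- sample_test_set(p, cfg, seed = 11, materialize = FALSE)
  expect_identical(nrow(plan), 300L)
  expect_true(all(plan$patient_id == p$patient_id))
  expect_identical(plan, sample_test_set(p, cfg, seed = 11,
                                         materialize = FALSE))
  one <- sample_test_set(p, sampling_config(10, n_test_per_patient = 1),
                         seed = 1, materialize = FALSE)
  expect_identical(nrow(one), 1L)
})
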