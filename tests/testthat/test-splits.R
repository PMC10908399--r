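test_that("factor ordering sorts ascending with patient-id tie-break", {
  meta <- data.frame(patient_id = c("p1", "p2", "p3"),
                     age_years = c(50, 43, 71),
                     bmi = c(22, 22, 21),
                     session_date = c(3, 1, 2),
                     alcohol_g_per_day = c(0, 10, 5),
                     eda_score = c(NA, NA, NA))
  expect_identical(order_patients(meta, "age"), c("p2", "p1", "p3"))
  # equal BMI: lexicographic patient-id tie-break
  expect_identical(order_patients(meta, "bmi"), c("p3", "p1", "p2"))
  # CHR is ordering by session date
  expect_identical(order_patients(meta, "chr"),
                   meta$patient_id[order(meta$session_date)])
  expect_error(order_patients(meta, "eda"), "eda")
  expect_error(order_patients(meta, "height"), "unknown factor")
})

test_that("ordered and balanced division follow the stated constructions", {
  ranked <- sprintf("p%02d", 1:10)
  d_ord <- divide_groups(ranked, k = 5, mode = "ordered")
  expect_identical(unname(d_ord$assignment), rep(1:5, each = 2L))
  d_bal <- divide_groups(ranked, k = 5, mode = "balanced")
  expect_identical(unname(d_bal$assignment), rep(1:5, times = 2L))
  # group g holds ranks {g, g+5} under balanced
  expect_identical(names(d_bal$assignment)[d_bal$assignment == 2L],
                   c("p02", "p07"))
  # 85 patients: five groups of 17 under either mode
  r85 <- sprintf("q%03d", 1:85)
  for (m in c("ordered", "balanced")) {
    d <- divide_groups(r85, 5, m)
    expect_true(all(table(d$assignment) == 17L))
  }
  expect_error(divide_groups(ranked[1:4], k = 5), "cannot divide")
})

test_that("division invariants hold across seeded cohorts; balanced spreads factors", {
  var_ord <- var_bal <- numeric(20)
  for (s in 1:20) {
    set.seed(s)
    n <- sample(20:40, 1)
    meta <- data.frame(patient_id = sprintf("p%03d", 1:n),
                       age_years = round(rnorm(n, 70, 10)),
                       bmi = rnorm(n, 22, 3),
                       session_date = sample(n),
                       alcohol_g_per_day = rexp(n, 1 / 15),
                       eda_score = runif(n))
    ranked <- order_patients(meta, "age")
    vals <- meta$age_years[match(ranked, meta$patient_id)]
    d_ord <- divide_groups(ranked, 5, "ordered")
    d_bal <- divide_groups(ranked, 5, "balanced")
    for (d in list(d_ord, d_bal)) {
      sizes <- table(d$assignment)
      expect_lte(max(sizes) - min(sizes), 1L)
      expect_setequal(names(d$assignment), meta$patient_id)
    }
    # ordered groups are contiguous in rank: max rank of group i < min of i+1
    rk <- match(names(d_ord$assignment), ranked)
    expect_true(all(tapply(rk, d_ord$assignment, max)[-5] <
                      tapply(rk, d_ord$assignment, min)[-1]))
    # balanced groups are stride assignments
    expect_true(all(unname(d_bal$assignment) == ((seq_len(n) - 1L) %% 5L) + 1L))
    var_ord[s] <- var(tapply(vals, d_ord$assignment, mean))
    var_bal[s] <- var(tapply(vals, d_bal$assignment, mean))
  }
  expect_true(mean(var_bal < var_ord) == 1)
})

test_that("role allotments enumerate all ordered (test, validation) pairs", {
  a5 <- enumerate_allotments(5)
  expect_length(a5, 20L)
  expect_length(enumerate_allotments(3), 6L)
  a4 <- enumerate_allotments(4)
  expect_length(a4, 12L)
  expect_true(all(vapply(a4, function(a) length(a$training), 0L) == 2L))
  # brute-force oracle: all ordered pairs, no duplicates, roles partition
  pairs <- vapply(a5, function(a) sprintf("%d_%d", a$test, a$validation), "")
  oracle <- as.vector(outer(1:5, 1:5, function(t, v)
    ifelse(t == v, NA, sprintf("%d_%d", t, v))))
  expect_setequal(pairs, oracle[!is.na(oracle)])
  for (a in a5)
    expect_setequal(c(a$test, a$validation, a$training), 1:5)
  expect_error(enumerate_allotments(2), ">= 3")
})

test_that("leakage audit passes clean batches and flags planted violations", {
  ranked <- sprintf("p%02d", 1:10)
  division <- divide_groups(ranked, 5, "balanced")
  allot <- enumerate_allotments(5)[[1]]   # test 1, validation 2
  train_ids <- names(division$assignment)[division$assignment %in%
                                            allot$training]
  clean <- rbind(data.frame(patient_id = train_ids, role = "training"),
                 data.frame(patient_id = names(division$assignment)[
                   division$assignment == allot$test], role = "test"))
  expect_true(check_leakage(division, allot, clean)$pass)
  planted <- rbind(clean, data.frame(patient_id = train_ids[1],
                                     role = "test"))
  rep_ <- check_leakage(division, allot, planted)
  expect_false(rep_$pass)
  expect_identical(rep_$offenders, train_ids[1])
  # empty batch set passes vacuously
  empty <- data.frame(patient_id = character(0), role = character(0))
  expect_true(check_leakage(division, allot, empty)$pass)
})
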