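two_group_matrix <- function(values_a, values_b, ids = NULL) {
  va <- rbind(values_a); vb <- rbind(values_b)
  values <- cbind(va, vb)
  rownames(values) <- ids %||% sprintf("t%02d", seq_len(nrow(values)))
  colnames(values) <- c(sprintf("A%d", seq_len(ncol(va))),
                        sprintf("B%d", seq_len(ncol(vb))))
  make_matrix(values, setNames(rep(c("A", "B"), c(ncol(va), ncol(vb))),
                               colnames(values)))
}

test_that("t-test matches the closed-form pooled-variance formula", {
  set.seed(44)
  for (i in 1:30) {
    na <- sample(2:5, 1); nb <- sample(2:5, 1)
    x <- rnorm(na, 50, 10); y <- rnorm(nb, 60, 12)
    values <- matrix(c(x, y), nrow = 1,
                     dimnames = list("t1", sprintf("s%d", 1:(na + nb))))
    cm <- make_matrix(values, setNames(rep(c("A", "B"), c(na, nb)),
                                       colnames(values)))
    res <- differential_test(cm, min_reads = 0)
    oracle <- brute_t(x, y)
    expect_equal(res$p_value, oracle$p, tolerance = 1e-10)
    # and agrees with stats::t.test as a second, independent route
    expect_equal(res$p_value,
                 t.test(x, y, var.equal = TRUE)$p.value, tolerance = 1e-10)
  }
})

test_that("the three filters act on the toy strong-signal transcript", {
  cm <- two_group_matrix(matrix(c(100, 110, 90), 1),
                         matrix(c(10, 12, 8), 1), ids = "X")
  res <- differential_test(cm, alpha = 0.1, min_fold = 2, min_reads = 7)
  expect_equal(res$fold_change, 10)           # 100 / 10
  expect_equal(res$direction, "A")
  expect_true(res$passes_threshold)
  expect_true(res$passes_fold)
  oracle <- brute_t(c(100, 110, 90), c(10, 12, 8))
  expect_equal(res$p_value, oracle$p, tolerance = 1e-10)
  expect_equal(oracle$df, 4)
  expect_equal(res$called, oracle$p <= 0.1)
})

test_that("identical groups yield zero calls and undefined p where constant", {
  values <- matrix(rep(c(5, 9, 13), 6), nrow = 3,
                   dimnames = list(c("t1", "t2", "t3"), sprintf("s%d", 1:6)))
  cm <- make_matrix(values, setNames(rep(c("A", "B"), each = 3),
                                     colnames(values)))
  res <- differential_test(cm, min_reads = 0)
  expect_equal(sum(res$called), 0)
  # replicate values are constant within groups: pooled variance is zero
  expect_true(all(is.na(res$p_value)))
  expect_false(any(res$passes_p))
})

test_that("zero means give infinite or undefined fold changes", {
  cm <- two_group_matrix(rbind(c(50, 60, 70), c(0, 0, 0)),
                         rbind(c(0, 0, 0), c(0, 0, 0)),
                         ids = c("on_off", "silent"))
  res <- differential_test(cm, min_reads = 7)
  expect_equal(res$fold_change, c(Inf, NA_real_))
  expect_true(res$passes_fold[1])     # Inf passes any finite min_fold
  expect_false(res$passes_fold[2])    # undefined, never called
  expect_false(res$called[2])
  expect_error(fold_change(-1, 5), "non-negative")
})

test_that("call counts are monotone in alpha, min_fold, and threshold", {
  sim <- generate_counts(sim_spec(n_transcripts = 300, seed = 7))
  cm <- normalize_and_sum(sim$runs)
  n_calls <- function(alpha, fold, thr) {
    sum(differential_test(cm, alpha = alpha, min_fold = fold,
                          min_reads = thr)$called)
  }
  base <- n_calls(0.1, 2, 7)
  expect_lte(n_calls(0.05, 2, 7), base)   # lower alpha
  expect_lte(n_calls(0.1, 4, 7), base)    # higher fold
  expect_lte(n_calls(0.1, 2, 50), base)   # higher threshold
  expect_lte(n_calls(0.01, 8, 100), n_calls(0.05, 4, 50))
})

test_that("swapping group labels flips direction but not p or fold", {
  sim <- generate_counts(sim_spec(n_transcripts = 200, seed = 8))
  cm <- normalize_and_sum(sim$runs)
  cm_swapped <- cm
  cm_swapped$groups <- setNames(
    ifelse(cm$groups == "IVV", "IVM", "IVV"), names(cm$groups))
  a <- differential_test(cm, min_reads = 7)
  b <- differential_test(cm_swapped, min_reads = 7)
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$fold_change, b$fold_change)
  expect_equal(a$called, b$called)
  flip <- !is.na(a$direction)
  expect_true(all(a$direction[flip] != b$direction[flip]))
})

test_that("summaries count calls by direction and filter failures", {
  cm <- two_group_matrix(
    rbind(c(100, 110, 90), c(10, 11, 9), c(200, 190, 210)),
    rbind(c(10, 12, 8), c(100, 90, 110), c(201, 189, 211)),
    ids = c("up_a", "up_b", "flat"))
  res <- differential_test(cm, min_reads = 7)
  s <- summarize_calls(res)
  expect_equal(s$n_tested, 3)
  expect_equal(s$n_called, 2)
  expect_equal(unname(s$by_direction[c("A", "B")]), c(1L, 1L))
  expect_equal(s$n_fail_fold, 1)
  empty <- summarize_calls(res[0, ])
  expect_equal(empty$n_called, 0)
  expect_equal(empty$n_tested, 0)
})

test_that("planted differential transcripts are recovered at high fold", {
  # 20 seeds, 50 planted transcripts at fold 8 and high expression:
  # the mean number of calls stays within 10% of the planted count
  n_called <- vapply(1:20, function(s) {
    sim <- generate_counts(sim_spec(
      n_transcripts = 500, baseline_mean_log_mu = log(200),
      baseline_mean_log_sigma = 0.5, dispersion = 0.02,
      de_fraction = 0.1, fold_change_set = 8, seed = 100 + s))
    cm <- normalize_and_sum(sim$runs)
    thr <- detection_threshold(sim$runs)
    summarize_calls(differential_test(cm, min_reads = thr))$n_called
  }, numeric(1))
  expect_gt(mean(n_called), 0.9 * 50)
  expect_lt(mean(n_called), 1.1 * 50)
})

test_that("degenerate group structure is rejected", {
  values <- matrix(1:4, 1, dimnames = list("t1", sprintf("s%d", 1:4)))
  cm3 <- make_matrix(values,
                     setNames(c("A", "A", "A", "B"), colnames(values)))
  expect_error(differential_test(cm3, min_reads = 0), ">= 2")
  cm1 <- make_matrix(values, setNames(rep("A", 4), colnames(values)))
  expect_error(differential_test(cm1, min_reads = 0), "two groups")
})
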