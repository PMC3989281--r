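test_that("normalization factors are min-total ratios anchored at 1", {
  expect_equal(compute_normalization_factors(c(A = 100, B = 100)),
               c(A = 1.0, B = 1.0))
  expect_equal(compute_normalization_factors(c(A = 100, B = 200)),
               c(A = 1.0, B = 0.5))
  expect_equal(compute_normalization_factors(c(A = 300, B = 150, C = 600)),
               c(A = 0.5, B = 1.0, C = 0.25))
})

test_that("degenerate run totals are rejected with the offending run named", {
  expect_error(compute_normalization_factors(numeric(0)), "no runs")
  expect_error(compute_normalization_factors(c(A = 100, B = 0)), "B")
  expect_error(compute_normalization_factors(c(bad = -5, ok = 10)), "bad")
})

test_that("factors are invariant under uniform rescaling of all totals", {
  totals <- c(a = 123, b = 456, c = 789)
  expect_equal(compute_normalization_factors(totals * 7.5),
               compute_normalization_factors(totals))
})

test_that("normalize_and_sum combines runs as factor-weighted sums", {
  counts <- cbind(r1 = c(t1 = 10L, t2 = 0L), r2 = c(t1 = 40L, t2 = 0L))
  runs <- make_runs(counts, samples = c("s1", "s1"), groups = c("G", "G"))
  cm <- normalize_and_sum(runs, factors = c(r1 = 1.0, r2 = 0.5))
  expect_equal(cm$values["t1", "s1"], 30.0)   # 10*1 + 40*0.5
  expect_equal(cm$values["t2", "s1"], 0.0)    # all-zero transcript stays 0

  # identical runs, both factors 1 -> entry is twice the raw count
  counts2 <- cbind(r1 = c(t1 = 7L), r2 = c(t1 = 7L))
  runs2 <- make_runs(counts2, c("s1", "s1"), c("G", "G"))
  cm2 <- normalize_and_sum(runs2, factors = c(r1 = 1, r2 = 1))
  expect_equal(unname(cm2$values["t1", "s1"]), 14)
})

test_that("normalization equalizes run totals and conserves mass", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(20:60, 1)
    n_samples <- sample(2:4, 1) * 2
    counts <- matrix(rpois(n * n_samples * 2, rexp(n, 1 / 50)),
                     nrow = n,
                     dimnames = list(sprintf("t%03d", 1:n),
                                     sprintf("r%02d", 1:(n_samples * 2))))
    storage.mode(counts) <- "integer"
    counts[1, ] <- counts[1, ] + 1L  # no empty run
    samples <- rep(sprintf("s%d", 1:n_samples), each = 2)
    groups <- rep(c("A", "B"), each = n_samples)
    runs <- make_runs(counts, samples, groups)
    f <- compute_normalization_factors(runs)
    scaled_totals <- colSums(sweep(counts, 2, f, `*`))
    expect_equal(unname(scaled_totals),
                 rep(min(runs$totals), ncol(counts)),
                 tolerance = 1e-9)
    cm <- normalize_and_sum(runs, f)
    # mass conservation: per-sample column sums equal the summed scaled
    # totals of that sample's runs
    for (s in colnames(cm$values)) {
      rids <- runs$manifest$run_id[runs$manifest$sample_id == s]
      expect_equal(sum(cm$values[, s]), sum((f * runs$totals)[rids]))
    }
  }
})

test_that("mismatched runs and manifests are rejected", {
  counts <- cbind(r1 = c(t1 = 1L), r2 = c(t1 = 2L), r3 = c(t1 = 3L))
  man3 <- data.frame(run_id = c("r1", "r2", "r9"),
                     sample_id = c("s1", "s1", "s2"),
                     group = c("A", "A", "B"))
  expect_error(run_counts(counts, man3), "r9")
  runs <- make_runs(counts, c("s1", "s1", "s2"), c("A", "A", "B"))
  expect_error(normalize_and_sum(runs, factors = c(r1 = 1, r2 = 1)),
               "no factor.*r3")
  expect_error(normalize_and_sum(runs,
                                 factors = c(r1 = 1, r2 = 1, r3 = 1)),
               "same number of runs")
  expect_error(run_counts(cbind(r1 = c(t1 = -1L)),
                          data.frame(run_id = "r1", sample_id = "s1",
                                     group = "A")),
               "non-negative")
})

test_that("detection threshold matches a brute-force scan of the CI bound", {
  # zero pooled variance: any positive integer mean exceeds the interval
  expect_equal(threshold_from_ingredients(0, df = 5, n = 3), 1L)
  # constructed half-width of 6.4 -> threshold 7
  conf <- 0.95
  df <- 5; n <- 3
  pv <- (6.4 / qt((1 + conf) / 2, df))^2 * n
  expect_equal(threshold_from_ingredients(pv, df, n, conf), 7L)
  expect_equal(brute_threshold(pv, df, n, conf), 7L)
  set.seed(22)
  for (i in 1:50) {
    pv <- rexp(1, 1 / 30)
    df <- sample(1:10, 1)
    n <- sample(2:6, 1)
    conf <- sample(c(0.9, 0.95, 0.99), 1)
    expect_equal(threshold_from_ingredients(pv, df, n, conf),
                 brute_threshold(pv, df, n, conf))
  }
})

test_that("threshold never decreases when pooled variance doubles", {
  set.seed(33)
  for (i in 1:50) {
    pv <- rexp(1, 1 / 20)
    df <- sample(2:8, 1)
    n <- sample(2:5, 1)
    expect_gte(threshold_from_ingredients(2 * pv, df, n),
               threshold_from_ingredients(pv, df, n))
  }
})

test_that("data-level threshold pools between-run variance over nonzero transcripts", {
  # identical technical runs -> zero pooled variance -> threshold 1
  counts <- cbind(r1 = c(t1 = 5L, t2 = 9L), r2 = c(t1 = 5L, t2 = 9L),
                  r3 = c(t1 = 5L, t2 = 9L), r4 = c(t1 = 5L, t2 = 9L))
  runs <- make_runs(counts, c("s1", "s1", "s2", "s2"), c("A", "A", "B", "B"))
  thr <- detection_threshold(runs, factors = setNames(rep(1, 4),
                                                      colnames(counts)))
  expect_equal(thr$pooled_variance, 0)
  expect_equal(thr$threshold, 1L)

  # hand-checkable: two transcripts, run pairs differing by known amounts
  counts2 <- cbind(r1 = c(t1 = 10L, t2 = 0L), r2 = c(t1 = 14L, t2 = 0L),
                   r3 = c(t1 = 20L, t2 = 0L), r4 = c(t1 = 26L, t2 = 0L))
  runs2 <- make_runs(counts2, c("s1", "s1", "s2", "s2"),
                     c("A", "A", "B", "B"))
  f1 <- setNames(rep(1, 4), colnames(counts2))
  thr2 <- detection_threshold(runs2, factors = f1)
  # t2 is all-zero so it is excluded; t1 pair variances are 8 and 18
  expect_equal(thr2$pooled_variance, mean(c(var(c(10, 14)), var(c(20, 26)))))
  expect_equal(thr2$df, 1L)
  expect_equal(thr2$threshold,
               brute_threshold(thr2$pooled_variance, thr2$df, thr2$n))
})

test_that("single-run samples make the threshold inestimable", {
  counts <- cbind(r1 = c(t1 = 5L), r2 = c(t1 = 6L), r3 = c(t1 = 7L))
  runs <- make_runs(counts, c("s1", "s1", "s2"), c("A", "A", "B"))
  expect_error(detection_threshold(runs), "single run")
})

test_that("contamination verdict compares group means to the threshold", {
  values <- rbind(CYP19A1 = c(0.53, 0.53, 0.53, 0.08, 0.08, 0.08),
                  OTHER = rep(100, 6))
  colnames(values) <- sprintf("s%d", 1:6)
  cm <- make_matrix(values, setNames(rep(c("IVV", "IVM"), each = 3),
                                     colnames(values)))
  v <- contamination_check(cm, "CYP19A1", 7)
  expect_true(v$pass)
  expect_equal(sort(unname(v$group_means)), c(0.08, 0.53))

  values["CYP19A1", 1:3] <- 10
  cm2 <- make_matrix(values, cm$groups)
  expect_false(contamination_check(cm2, "CYP19A1", 7)$pass)
  expect_error(contamination_check(cm, "ABSENT", 7), "absent")
})
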