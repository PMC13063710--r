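test_that("confusion counts tally the four outcomes", {
  c1 <- confusion_counts(c(1, 0), c(1, 0))
  expect_identical(unlist(unclass(c1)), c(TP = 1L, TN = 1L, FP = 0L, FN = 0L))
  c2 <- confusion_counts(c(1, 1, 0, 0), c(0, 0, 1, 1))
  expect_identical(unlist(unclass(c2)), c(TP = 0L, TN = 0L, FP = 2L, FN = 2L))
  c3 <- confusion_counts(c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0),
                         c(1, 1, 1, 1, 0, 0, 0, 0, 0, 1))
  expect_identical(unlist(unclass(c3)), c(TP = 3L, TN = 5L, FP = 2L, FN = 0L))
  expect_identical(with(c3, TP + TN + FP + FN), 10L)
  expect_error(confusion_counts(c(1, 0), c(1)), "length")
})

test_that("classification metrics follow their printed formulas", {
  perfect <- confusion_counts(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(unlist(classification_metrics(perfect)),
               c(accuracy = 1, balanced_accuracy = 1, f1 = 1))
  m <- classification_metrics(
    structure(list(TP = 3L, TN = 5L, FP = 1L, FN = 1L),
              class = "confusion_counts"))
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$balanced_accuracy, (0.75 + 5 / 6) / 2)
  expect_equal(m$balanced_accuracy, 0.7917, tolerance = 1e-4)
  expect_equal(m$f1, 0.75)
  # F1 defined 0 when TP = 0
  z <- classification_metrics(
    structure(list(TP = 0L, TN = 5L, FP = 0L, FN = 2L),
              class = "confusion_counts"))
  expect_identical(z$f1, 0)
  expect_error(classification_metrics(
    structure(list(TP = 0L, TN = 5L, FP = 1L, FN = 0L),
              class = "confusion_counts")), "absent")
})

test_that("relative performance is a percentage of the baseline mean", {
  expect_equal(relative_performance(0.82, 0.82), 100)
  expect_equal(relative_performance(0.85, 0.82), 103.6585, tolerance = 1e-4)
  expect_gt(relative_performance(0.9, 0.82), 100)  # >100% is legal
  expect_error(relative_performance(0.5, 0), "> 0")
})

test_that("Wilcoxon exact branch reproduces hand-enumerable p-values", {
  # n = 15 uniformly signed pairs: p = 2 / 2^15
  b <- seq(0.1, 1.5, by = 0.1)
  w <- wilcoxon_signed_rank(b + b / 10, b)
  expect_identical(w$method, "exact")
  expect_equal(w$p_value, 2 / 2^15)
  expect_equal(w$p_value, 6.10e-5, tolerance = 1e-3)
  # n = 3, differences {1,2,3}: enumeration over 8 sign vectors gives 0.25
  w3 <- wilcoxon_signed_rank(c(1, 2, 3), c(0, 0, 0))
  expect_equal(w3$p_value, 0.25)
  # identical vectors: degenerate with warning
  expect_warning(w0 <- wilcoxon_signed_rank(1:4, 1:4), "identical")
  expect_equal(w0$p_value, 1)
  expect_error(wilcoxon_signed_rank(1:3, 1:4), "length")
})

test_that("exact branch matches full sign-flip enumeration for n <= 10", {
  withr::with_seed(202, {
    for (rep in 1:20) {
      n <- sample(3:10, 1)
      d <- round(rnorm(n), 3)
      d <- d[d != 0]
      if (any(duplicated(abs(d))) || length(d) < 3) next
      a <- cumsum(abs(rnorm(length(d)))) ; b <- a - d
      w <- wilcoxon_signed_rank(a, b)
      expect_identical(w$method, "exact")
      expect_equal(w$p_value, wilcoxon_enumeration_p(d), tolerance = 1e-12)
      # cross-check against the standard implementation on clean input
      ref <- stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)
      expect_equal(w$p_value, ref$p.value, tolerance = 1e-12)
    }
  })
})

test_that("tied or large samples use the corrected normal approximation", {
  a <- c(5, 6, 7, 8, 9, 10, 11, 12)
  b <- a - c(1, 1, 2, 2, 3, 3, 4, 4)  # tied absolute differences
  w <- wilcoxon_signed_rank(a, b)
  expect_identical(w$method, "normal_approximation")
  ref <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                             exact = FALSE, correct = TRUE))
  expect_equal(w$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("Holm step-down adjustment matches hand-worked families", {
  # smallest of a 3-family is tripled
  p <- c(6.10e-5, 0.02, 0.9)
  adj <- holm_adjust(p)
  expect_equal(adj[1], 1.83e-4)
  expect_identical(holm_adjust(0.03), 0.03)
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  # monotone along sorted raw p, never below raw
  withr::with_seed(9, {
    raw <- runif(8)
    adj <- holm_adjust(raw)
    expect_true(all(adj >= raw))
    expect_true(all(diff(adj[order(raw)]) >= -1e-12))
  })
  expect_error(holm_adjust(c(0.5, 0)), "\\(0, 1\\]")
})

test_that("effect size r recovers the published magnitudes from p and n", {
  expect_equal(effect_size_r(6.103515625e-05, 15, -1), -1.04, tolerance = 0.005)
  expect_equal(effect_size_r(6.53e-4, 15, -1), -0.88, tolerance = 0.005)
  expect_identical(effect_size_r(1, 15), 0)
})

test_that("the benchmark planner enumerates the full factorial design", {
  plan <- plan_runs(c("dynamic", "exhaustive", "imputation", "hybrid"),
                    builtin_configs(), 1:15)
  expect_identical(nrow(plan), 900L)
  expect_identical(sum(plan$approach == "hybrid"), 225L)
  expect_identical(length(unique(plan$scenario)), 5L)
  expect_identical(nrow(unique(plan[, c("scenario", "config_id")])), 15L)
})

test_that("a smoke benchmark populates every cell and is reproducible", {
  gs <- generator_spec(120, c(rs = 4, cn = 4, mu = 4, pp = 4),
                       minority_fraction = 0.25, seed = 31)
  bc <- benchmark_config(
    generator = gs, approaches = c("dynamic", "imputation", "hybrid"),
    configs = builtin_configs()[1], seeds = 1:2,
    classifier = classifier_spec("fast_baseline"),
    test_fraction = 0.2, timing_repetitions = 1)
  rep1 <- run_benchmark(bc)
  expect_identical(nrow(rep1$runs), 6L)  # 3 approaches x 1 config x 2 seeds
  expect_false(anyNA(rep1$runs[, c("accuracy", "balanced_accuracy", "f1")]))
  expect_identical(nrow(rep1$baseline), 2L)
  # metric tables identical on re-run (timings are hardware noise)
  rep2 <- run_benchmark(bc)
  mcols <- c("approach", "scenario", "config_id", "seed",
             "accuracy", "balanced_accuracy", "f1")
  expect_identical(rep1$runs[, mcols], rep2$runs[, mcols])
  # comparisons table covers hybrid vs each other approach
  expect_setequal(unique(rep1$comparisons$comparison),
                  c("hybrid_vs_dynamic", "hybrid_vs_imputation"))
  expect_true(all(rep1$comparisons$p_holm >= rep1$comparisons$p_value))
  # baseline relative to itself is 100% for every metric
  agg <- rep1$aggregate
  base_mean <- colMeans(rep1$baseline[, c("accuracy", "balanced_accuracy", "f1")])
  for (m in names(base_mean)) {
    expect_equal(relative_performance(base_mean[[m]], base_mean[[m]]), 100)
  }
})
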