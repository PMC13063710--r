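#' Confusion counts for binary predictions
#'
#' @param y_true,y_pred equal-length 0/1 vectors; class 1 is positive
#' @return object of class `confusion_counts`: list with `TP`, `TN`, `FP`,
#'   `FN` summing to the number of evaluated samples
#' @export
confusion_counts <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (!all(c(y_true, y_pred) %in% c(0L, 1L))) stop("labels must be 0/1")
  structure(
    list(TP = sum(y_true == 1L & y_pred == 1L),
         TN = sum(y_true == 0L & y_pred == 0L),
         FP = sum(y_true == 0L & y_pred == 1L),
         FN = sum(y_true == 1L & y_pred == 0L)),
    class = "confusion_counts")
}

#' Accuracy, balanced accuracy and F1 from confusion counts
#'
#' `accuracy = (TP+TN)/total`; `balanced accuracy` is the mean of the two
#' per-class recalls (robust to class imbalance); `F1` is the harmonic mean
#' of precision and recall, defined 0 when `TP = 0`. Both classes must be
#' present in the true labels or balanced accuracy is undefined.
#'
#' @param c a [confusion_counts()]
#' @return named list with `accuracy`, `balanced_accuracy`, `f1`
#' @export
classification_metrics <- function(c) {
  total <- c$TP + c$TN + c$FP + c$FN
  if (total == 0L) stop("no evaluated samples")
  if (c$TP + c$FN == 0L || c$TN + c$FP == 0L) {
    stop("a class is absent from y_true; balanced accuracy undefined")
  }
  recall_pos <- c$TP / (c$TP + c$FN)
  recall_neg <- c$TN / (c$TN + c$FP)
  f1 <- if (c$TP == 0L) 0 else {
    precision <- c$TP / (c$TP + c$FP)
    2 * precision * recall_pos / (precision + recall_pos)
  }
  list(accuracy = (c$TP + c$TN) / total,
       balanced_accuracy = (recall_pos + recall_neg) / 2,
       f1 = f1)
}

#' Performance relative to the complete-data baseline, in percent
#' @param metric observed metric value
#' @param baseline_metric the baseline's seed-mean for the same metric,
#'   strictly positive
#' @return `metric / baseline_metric * 100`; values above 100 are legal
#'   (removing noisy blocks can beat the complete-data model)
#' @export
relative_performance <- function(metric, baseline_metric) {
  if (any(baseline_metric <= 0)) stop("baseline metric must be > 0")
  metric / baseline_metric * 100
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped; tied absolute differences receive average
#' ranks. The two-sided p-value is exact (by signed-rank enumeration) when
#' `n <= 25` with no ties, otherwise a normal approximation with tie and
#' continuity corrections is used. All-identical pairs give `p = 1` with a
#' warning.
#'
#' @param a,b equal-length paired numeric vectors (e.g. per-seed metric
#'   values of two approaches)
#' @return object of class `wilcoxon_result`: `statistic` (W, sum of ranks
#'   of positive differences), `z` (normal deviate recovered from p, signed
#'   by the median difference), `p_value`, `n_pairs` (after zero removal),
#'   `method`
#' @export
wilcoxon_signed_rank <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("all pairs identical; p = 1")
    return(structure(list(statistic = 0, z = 0, p_value = 1, n_pairs = 0L,
                          method = "degenerate"), class = "wilcoxon_result"))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))
  if (n <= 25L && !ties) {
    p_lower <- psignrank(W, n)
    p_upper <- 1 - psignrank(W - 1, n)
    p <- min(1, 2 * min(p_lower, p_upper))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    cc <- sign(W - mu) * 0.5
    z0 <- (W - mu - cc) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z0)))
    method <- "normal_approximation"
  }
  direction <- sign(stats::median(d))
  structure(
    list(statistic = W, z = direction * qnorm(1 - p / 2), p_value = p,
         n_pairs = n, method = method),
    class = "wilcoxon_result")
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank (%s): W = %g, n = %d, p = %.3g\n",
              x$method, x$statistic, x$n_pairs, x$p_value))
  invisible(x)
}

#' Holm-Bonferroni step-down adjustment
#'
#' @param p_values raw p-values in (0, 1]
#' @return adjusted p-values in input order: sorted ascending, the i-th is
#'   `max_{j<=i} (m-j+1) p_(j)`, capped at 1
#' @export
holm_adjust <- function(p_values) {
  if (any(p_values <= 0 | p_values > 1)) stop("p-values must be in (0, 1]")
  stats::p.adjust(p_values, method = "holm")
}

#' Effect size r for a Wilcoxon comparison
#'
#' `r = sign * qnorm(1 - p/2) / sqrt(n)`: the normal deviate recovered from
#' the two-sided p-value, scaled by the square root of the pair count and
#' signed by the direction of the median difference (negative = first
#' method lower). Magnitudes: small ~0.1-0.3, medium ~0.3-0.5, large >0.5;
#' exact small-n p-values can push `|r|` above 1.
#'
#' @param p two-sided p-value in (0, 1]
#' @param n_pairs number of pairs
#' @param direction +1 or -1 (sign of the median difference)
#' @return signed effect size
#' @export
effect_size_r <- function(p, n_pairs, direction = 1) {
  sign(direction) * qnorm(1 - p / 2) / sqrt(n_pairs)
}

#' Enumerate the runs of a benchmark design
#'
#' @param approaches character vector of strategy kinds
#' @param configs list of [scenario_config()]
#' @param seeds integer seed vector
#' @return data.frame with one row per (approach, scenario, config, seed)
#' @examples
#' nrow(plan_runs(c("dynamic", "exhaustive", "imputation", "hybrid"),
#'                builtin_configs(), 1:15)) # 900
#' @export
plan_runs <- function(approaches, configs, seeds) {
  grid <- expand.grid(
    seed = seeds,
    config_idx = seq_along(configs),
    approach = approaches,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$scenario <- vapply(configs, `[[`, character(1), "scenario")[grid$config_idx]
  grid$config_id <- vapply(configs, `[[`, integer(1), "config_id")[grid$config_idx]
  grid[, c("approach", "scenario", "config_id", "seed", "config_idx")]
}

#' Benchmark configuration
#'
#' @param generator a [generator_spec()] describing the synthetic dataset,
#'   or `NULL` when `dataset` is given
#' @param dataset a complete labelled [multiomics_dataset()]; overrides
#'   `generator`
#' @param approaches strategy kinds to evaluate
#' @param configs list of [scenario_config()]
#' @param seeds integer seeds; each drives split, injection, oversampling
#'   and model fits through independent derived streams
#' @param classifier a [classifier_spec()]
#' @param imputer an [imputer_config()]
#' @param test_fraction stratified hold-out fraction (default 0.05)
#' @param timing_repetitions wall-clock timing repetitions whose mean is
#'   reported (default 3)
#' @return list of class `benchmark_config`
#' @export
benchmark_config <- function(generator = NULL, dataset = NULL,
                             approaches = c("dynamic", "exhaustive",
                                            "imputation", "hybrid"),
                             configs = builtin_configs(), seeds = 1:15,
                             classifier = classifier_spec(),
                             imputer = imputer_config(),
                             test_fraction = 0.05,
                             timing_repetitions = 3L) {
  if (is.null(generator) && is.null(dataset)) {
    stop("either a generator spec or a dataset is required")
  }
  structure(
    list(generator = generator, dataset = dataset, approaches = approaches,
         configs = configs, seeds = as.integer(seeds),
         classifier = classifier, imputer = imputer,
         test_fraction = test_fraction,
         timing_repetitions = as.integer(timing_repetitions)),
    class = "benchmark_config")
}

time_mean <- function(reps, expr_fun) {
  times <- numeric(reps)
  result <- NULL
  for (r in seq_len(reps)) {
    t0 <- proc.time()[["elapsed"]]
    result <- expr_fun()
    times[r] <- proc.time()[["elapsed"]] - t0
  }
  list(result = result, time = mean(times))
}

#' Run a multi-seed benchmark of the missing-data strategies
#'
#' For each seed: stratified split, a complete-data baseline model, then
#' per scenario configuration: block-wise missingness injected separately
#' into train and test, each approach fitted and evaluated, fit/predict
#' wall-clock averaged over `timing_repetitions`. Deterministic given the
#' seed list and classifier backend.
#'
#' @param config a [benchmark_config()]
#' @return object of class `benchmark_report`: `runs` (tidy per-run
#'   data.frame), `baseline` (per-seed baseline metrics), `aggregate`
#'   (mean +/- SD and % of baseline mean per approach, overall and per
#'   scenario), `comparisons` (Wilcoxon/Holm/effect-size of hybrid vs each
#'   other approach, when hybrid is included)
#' @export
run_benchmark <- function(config) {
  for (cf in config$configs) {
    findings <- validate_config(cf)
    if (length(findings)) {
      stop("invalid config (", cf$scenario, " ", cf$config_id, "): ",
           paste(findings, collapse = "; "))
    }
  }
  ds <- config$dataset %||% generate_complete(config$generator)
  runs <- list()
  baseline_rows <- list()
  for (seed in config$seeds) {
    split <- stratified_split(ds, config$test_fraction,
                              derive_seed(seed, "split"))
    base_fit <- time_mean(config$timing_repetitions, function()
      fit_strategy(split$train, "dynamic", config$classifier,
                   config$imputer, seed))
    base_pred <- time_mean(config$timing_repetitions, function()
      predict_strategy(base_fit$result, split$test))
    bm <- classification_metrics(
      confusion_counts(split$test$labels, base_pred$result$labels))
    baseline_rows[[length(baseline_rows) + 1L]] <- data.frame(
      seed = seed, accuracy = bm$accuracy,
      balanced_accuracy = bm$balanced_accuracy, f1 = bm$f1,
      train_time_s = base_fit$time, test_time_s = base_pred$time)
    for (ci in seq_along(config$configs)) {
      cf <- config$configs[[ci]]
      inj_seed <- derive_seed(seed, paste("inject", cf$scenario, cf$config_id))
      train_m <- inject_missingness(split$train, cf$train_assignments,
                                    inj_seed, cf$remainder_policy)
      test_m <- inject_missingness(split$test, cf$test_assignments,
                                   derive_seed(inj_seed, "test"),
                                   cf$remainder_policy)
      for (approach in config$approaches) {
        fit <- time_mean(config$timing_repetitions, function()
          fit_strategy(train_m, approach, config$classifier,
                       config$imputer, seed))
        pred <- time_mean(config$timing_repetitions, function()
          predict_strategy(fit$result, test_m))
        m <- classification_metrics(
          confusion_counts(test_m$labels, pred$result$labels))
        runs[[length(runs) + 1L]] <- data.frame(
          approach = approach, scenario = cf$scenario,
          config_id = cf$config_id, seed = seed,
          accuracy = m$accuracy, balanced_accuracy = m$balanced_accuracy,
          f1 = m$f1, train_time_s = fit$time, test_time_s = pred$time,
          total_time_s = fit$time + pred$time,
          stringsAsFactors = FALSE)
      }
    }
  }
  runs <- do.call(rbind, runs)
  baseline <- do.call(rbind, baseline_rows)
  structure(
    list(runs = runs, baseline = baseline,
         aggregate = aggregate_runs(runs, baseline),
         comparisons = if ("hybrid" %in% config$approaches)
           compare_to_hybrid(runs)),
    class = "benchmark_report")
}

metric_cols <- c("accuracy", "balanced_accuracy", "f1")
timing_cols <- c("train_time_s", "test_time_s", "total_time_s")

#' Aggregate benchmark runs into mean +/- SD and relative-performance tables
#'
#' @param runs the `runs` data.frame of a [run_benchmark()] report
#' @param baseline the per-seed baseline data.frame
#' @return data.frame with one row per (approach, scenario or "overall"),
#'   mean and SD of each metric and timing, and each performance metric as
#'   a percentage of the baseline seed-mean
#' @export
aggregate_runs <- function(runs, baseline) {
  base_mean <- colMeans(baseline[, metric_cols])
  one <- function(sub, scen) {
    row <- data.frame(approach = sub$approach[1], scenario = scen)
    for (m in c(metric_cols, intersect(timing_cols, names(sub)))) {
      row[[paste0(m, "_mean")]] <- mean(sub[[m]])
      row[[paste0(m, "_sd")]] <- sd(sub[[m]])
    }
    for (m in metric_cols) {
      row[[paste0(m, "_pct_baseline")]] <-
        relative_performance(mean(sub[[m]]), base_mean[[m]])
    }
    row
  }
  out <- list()
  for (a in unique(runs$approach)) {
    sub <- runs[runs$approach == a, ]
    out[[length(out) + 1L]] <- one(sub, "overall")
    for (scen in unique(sub$scenario)) {
      out[[length(out) + 1L]] <- one(sub[sub$scenario == scen, ], scen)
    }
  }
  do.call(rbind, out)
}

#' Wilcoxon/Holm/effect-size comparison of the hybrid against each approach
#'
#' Overall comparisons pair per-(scenario, config, seed) values; per-scenario
#' comparisons first average configurations within each seed so pairs are
#' matched seed indices. Holm correction is applied within each
#' (comparison, scope) family across its metrics.
#'
#' @param runs the `runs` data.frame of a [run_benchmark()] report
#' @return data.frame: comparison, scope, metric, n pairs, raw p, effect
#'   size r, Holm-adjusted p
#' @export
compare_to_hybrid <- function(runs) {
  others <- setdiff(unique(runs$approach), "hybrid")
  metrics <- c(metric_cols, intersect(c("train_time_s", "test_time_s"),
                                      names(runs)))
  key <- function(df) paste(df$scenario, df$config_id, df$seed)
  out <- list()
  for (other in others) {
    for (scope in c("overall", unique(runs$scenario))) {
      sub <- if (scope == "overall") runs else runs[runs$scenario == scope, ]
      h <- sub[sub$approach == "hybrid", ]
      o <- sub[sub$approach == other, ]
      rows <- list()
      for (m in metrics) {
        if (scope == "overall") {
          a <- h[[m]][order(key(h))]
          b <- o[[m]][order(key(o))]
        } else {
          a <- tapply(h[[m]], h$seed, mean)
          b <- tapply(o[[m]], o$seed, mean)
          b <- b[names(a)]
        }
        wt <- suppressWarnings(wilcoxon_signed_rank(a, b))
        direction <- sign(stats::median(a - b))
        if (direction == 0) direction <- 0
        rows[[m]] <- data.frame(
          comparison = paste0("hybrid_vs_", other), scope = scope,
          metric = m, n_pairs = wt$n_pairs, p_value = wt$p_value,
          effect_r = if (wt$n_pairs > 0)
            effect_size_r(wt$p_value, wt$n_pairs, direction) else 0,
          stringsAsFactors = FALSE)
      }
      fam <- do.call(rbind, rows)
      fam$p_holm <- holm_adjust(fam$p_value)
      out[[length(out) + 1L]] <- fam
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
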