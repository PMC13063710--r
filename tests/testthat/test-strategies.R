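fast <- classifier_spec("fast_baseline")

test_that("ensemble model inventories follow each strategy's contract", {
  ds <- toy_dataset(n = 120, seed = 21)
  tr <- inject_missingness(ds, list(list(pattern = "1011", fraction = 0.2),
                                    list(pattern = "0110", fraction = 0.2)),
                           seed = 5)
  dyn <- fit_strategy(tr, "dynamic", fast, seed = 2)
  expect_setequal(dyn$trained_codes, c(15L, 11L, 6L))
  exh <- fit_strategy(tr, "exhaustive", fast, seed = 2)
  # complete samples exist, so every enumerated subset is non-empty
  expect_identical(sort(exh$trained_codes), 1:15)
  imp <- fit_strategy(tr, "imputation", fast, seed = 2)
  expect_identical(imp$trained_codes, 15L)
  expect_identical(imp$models[["15"]]$feats, colnames(ds$values))
  # per-model feature scope equals the blocks with bit 1
  m11 <- dyn$models[["11"]]
  expect_identical(m11$feats, block_features(ds, c("rs", "mu", "pp")))
})

test_that("a single-profile training set trains exactly its containment subsets", {
  ds <- toy_dataset(n = 80, seed = 22)
  tr <- inject_missingness(ds, list(list(pattern = "1010", fraction = 1.0)),
                           seed = 5)
  dyn <- fit_strategy(tr, "dynamic", fast, seed = 2)
  expect_identical(dyn$trained_codes, 10L)
  exh <- fit_strategy(tr, "exhaustive", fast, seed = 2)
  # non-empty subsets are exactly the non-zero q contained in 1010
  expect_setequal(exh$trained_codes, c(2L, 8L, 10L))
})

test_that("hybrid routing picks exact, minimal-superset or subset candidates", {
  r1 <- route_hybrid(to_decimal(c(0,1,0,1)), c(15L, 7L, 5L), 4)
  expect_identical(r1$mode, "exact")
  expect_identical(r1$candidates, 5L)
  r2 <- route_hybrid(to_decimal(c(0,1,0,1)), c(15L, 7L, 13L), 4)
  expect_identical(r2$mode, "impute_superset")
  expect_identical(r2$candidates, c(7L, 13L))
  expect_identical(r2$distance, 1L)
  r3 <- route_hybrid(to_decimal(c(1,1,1,0)), c(2L, 4L, 8L), 4)
  expect_identical(r3$mode, "subset_fallback")
  expect_identical(r3$candidates, c(2L, 4L, 8L))
  expect_identical(r3$distance, 2L)
  expect_error(route_hybrid(to_decimal(c(1,0,0,0)), c(6L), 4), "compatible")
})

test_that("majority voting follows strict majority then the tie-break chain", {
  expect_identical(majority_vote(c(1L, 1L, 0L)), 1L)
  expect_identical(majority_vote(1L), 1L)
  # even split: candidate with the largest training subset wins
  expect_identical(majority_vote(c(1L, 0L), subset_sizes = c(40, 25),
                                 codes = c(9L, 3L)), 1L)
  expect_identical(majority_vote(c(1L, 0L), subset_sizes = c(25, 40),
                                 codes = c(9L, 3L)), 0L)
  # equal sizes: smallest profile code wins
  expect_identical(majority_vote(c(1L, 0L), subset_sizes = c(30, 30),
                                 codes = c(9L, 3L)), 0L)
  expect_error(majority_vote(integer(0)), "empty")
})

test_that("consensus tie-break maps the averaged sample to the nearest centroid", {
  ds <- toy_dataset(n = 100, seed = 23)
  tr <- inject_missingness(ds, list(list(pattern = "1100", fraction = 0.3),
                                    list(pattern = "0011", fraction = 0.3)),
                           seed = 5)
  ens <- fit_strategy(tr, "hybrid", fast, seed = 2)
  v1 <- masked_values(ds)[1, ]
  expect_equal(unname(colMeans(rbind(v1 * 0, v1 * 0 + 1))),
               rep(0.5, length(v1)))  # arithmetic-mean consensus
  # two identical versions: consensus equals either and prediction is defined
  lab <- consensus_tiebreak(rbind(v1, v1), ens)
  expect_true(lab %in% 0:1)
  # nearer centroid's model is selected: build a consensus equal to the
  # centroid of one trained profile's subset on its scope
  q <- ens$trained_codes[1]
  members <- which(bitwAnd(ens$sample_codes, q) == q)
  centroid_row <- colMeans(masked_values(tr)[members, , drop = FALSE], na.rm = TRUE)
  centroid_row[is.na(centroid_row)] <- 0
  lab2 <- consensus_tiebreak(rbind(centroid_row, centroid_row), ens)
  expect_true(lab2 %in% 0:1)
  expect_error(consensus_tiebreak(rbind(v1), ens), ">= 2")
})

test_that("shared profiles give identical dynamic/exhaustive/hybrid predictions", {
  ds <- toy_dataset(n = 150, seed = 24)
  cfg <- builtin_configs()[[2]]  # same patterns, both sides
  sp <- stratified_split(ds, 0.2, seed = 6)
  tr <- inject_missingness(sp$train, cfg$train_assignments, 7)
  te <- inject_missingness(sp$test, cfg$test_assignments, 8)
  preds <- lapply(c("dynamic", "exhaustive", "hybrid"), function(k)
    predict_strategy(fit_strategy(tr, k, fast, seed = 3), te))
  expect_identical(preds[[1]]$labels, preds[[2]]$labels)
  expect_identical(preds[[1]]$labels, preds[[3]]$labels)
  expect_true(all(preds[[3]]$audit$mode == "exact"))
})

test_that("hybrid imputes only on superset routes and never retrains", {
  ds <- toy_dataset(n = 200, seed = 25)
  sp <- stratified_split(ds, 0.25, seed = 6)
  cfg <- builtin_configs()[[10]]  # missing omic config 1
  tr <- inject_missingness(sp$train, cfg$train_assignments, 7)
  te <- inject_missingness(sp$test, cfg$test_assignments, 8, "renormalize")
  ens <- fit_strategy(tr, "hybrid", fast, seed = 3)
  out <- predict_strategy(ens, te)
  expect_true(all(out$audit$mode %in%
                    c("exact", "impute_superset", "subset_fallback")))
  expect_false(any(out$audit$mode == "retrain"))
  expect_true(any(out$audit$mode == "impute_superset"))
})

test_that("dynamic retraining happens once per unseen profile and is cached", {
  ds <- toy_dataset(n = 200, seed = 26)
  sp <- stratified_split(ds, 0.25, seed = 6)
  cfg <- builtin_configs()[[10]]
  tr <- inject_missingness(sp$train, cfg$train_assignments, 7)
  te <- inject_missingness(sp$test, cfg$test_assignments, 8, "renormalize")
  ens <- fit_strategy(tr, "dynamic", fast, seed = 3)
  out <- predict_strategy(ens, te)
  retrained <- out$audit[out$audit$mode == "retrain", ]
  expect_gt(nrow(retrained), 0)
  # exactly one training event per distinct unseen profile
  events <- tapply(retrained$trained_new, retrained$profile_code, sum)
  expect_true(all(events == 1L))
  # second pass over the same data hits the cache only
  out2 <- predict_strategy(ens, te)
  expect_false(any(out2$audit$trained_new))
  expect_identical(out2$labels, out$labels)
})

test_that("the imputation strategy completes test samples before predicting", {
  ds <- toy_dataset(n = 120, seed = 27)
  sp <- stratified_split(ds, 0.2, seed = 6)
  tr <- inject_missingness(sp$train,
                           list(list(pattern = "1011", fraction = 0.3)), 7)
  te <- inject_missingness(sp$test,
                           list(list(pattern = "0111", fraction = 0.5)), 8)
  ens <- fit_strategy(tr, "imputation", fast, seed = 3)
  out <- predict_strategy(ens, te)
  expect_true(all(out$audit$mode == "imputed"))
  expect_length(out$labels, n_samples(te))
  expect_true(all(out$labels %in% 0:1))
})
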