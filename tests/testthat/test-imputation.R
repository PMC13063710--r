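test_that("KNN completion reproduces hand-computed toy fills", {
  donors <- rbind(c(0, 0), c(1, 1))
  colnames(donors) <- c("f1", "f2")
  # nearest donor copy at k=1: query closer to donor 1
  q <- c(f1 = 0.1, f2 = NA)
  expect_equal(unname(knn_impute(q, donors, imputer_config(k = 1))[1, "f2"]),
               0)
  # symmetric inverse-distance weights -> midpoint
  q2 <- c(f1 = 0.5, f2 = NA)
  expect_equal(unname(knn_impute(q2, donors, imputer_config(k = 2))[1, "f2"]),
               0.5)
  # no missing cells -> identity
  full <- rbind(c(0.2, 0.8))
  colnames(full) <- c("f1", "f2")
  expect_identical(knn_impute(full, donors, imputer_config()), full)
})

test_that("KNN completion matches the brute-force reference on random instances", {
  withr::with_seed(101, {
    for (rep in 1:50) {
      n <- sample(4:20, 1); d <- sample(2:8, 1); k <- sample(1:5, 1)
      donors <- matrix(runif(n * d), n, d,
                       dimnames = list(NULL, paste0("f", 1:d)))
      donors[runif(n * d) < 0.15] <- NA
      # every feature needs >= 1 observed donor; every donor >= 1 value
      for (j in seq_len(d)) if (all(is.na(donors[, j]))) donors[1, j] <- runif(1)
      for (i in seq_len(n)) if (all(is.na(donors[i, ]))) donors[i, 1] <- runif(1)
      x <- matrix(runif(3 * d), 3, d, dimnames = list(NULL, paste0("f", 1:d)))
      x[cbind(1:3, sample(d, 3, replace = TRUE))] <- NA
      got <- knn_impute(x, donors, imputer_config(k = k))
      want <- knn_oracle(x, donors, k)
      expect_equal(got, want, tolerance = 1e-10)
    }
  })
})

test_that("k = 1 completion equals explicit nearest-neighbour copy", {
  withr::with_seed(55, {
    donors <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("f", 1:4)))
    x <- c(rnorm(3), NA); names(x) <- paste0("f", 1:4)
    got <- knn_impute(x, donors, imputer_config(k = 1))[1, "f4"]
    dists <- apply(donors, 1, function(r) sqrt(sum((r[1:3] - x[1:3])^2)))
    expect_equal(unname(got), unname(donors[which.min(dists), "f4"]))
  })
})

test_that("completion preserves observed cells bit-identically", {
  withr::with_seed(77, {
    donors <- matrix(runif(60), 12, 5, dimnames = list(NULL, paste0("f", 1:5)))
    x <- matrix(runif(20), 4, 5, dimnames = list(NULL, paste0("f", 1:5)))
    x[c(2, 7, 13, 18)] <- NA
    out <- knn_impute(x, donors, imputer_config())
    expect_identical(out[!is.na(x)], x[!is.na(x)])
    expect_false(anyNA(out))
  })
})

test_that("completion errors when a feature has no donor at all", {
  donors <- cbind(f1 = c(0.5, 0.7), f2 = c(NA_real_, NA_real_))
  x <- c(f1 = 0.3, f2 = NA)
  expect_error(knn_impute(x, donors, imputer_config()), "f2")
})

blocks2 <- list(A = c("a1", "a2"), B = c("b1", "b2"))

test_that("profile refinement copies only the required missing blocks", {
  refs <- rbind(c(0.0, 0.1, 10, 11),
                c(0.9, 1.0, 20, 21))
  colnames(refs) <- c("a1", "a2", "b1", "b2")
  # test sample observed on block A, missing block B, target = both blocks
  x <- c(a1 = 0.1, a2 = 0.2, b1 = NA, b2 = NA)
  obs <- c(TRUE, TRUE, FALSE, FALSE)
  out <- refine_to_profile(x, obs, c(1L, 1L), refs, blocks2,
                           imputer_config(refine_mode = "single_nearest"))
  # nearest reference on observed scope (distances ~0.14 vs ~1.13) is row 1
  expect_equal(unname(out[c("b1", "b2")]), c(10, 11))
  expect_equal(unname(out[c("a1", "a2")]), c(0.1, 0.2))  # observed untouched
  # target already satisfied -> unchanged
  expect_identical(refine_to_profile(x, obs, c(1L, 0L), refs, blocks2), x)
  # single reference is the forced donor
  out1 <- refine_to_profile(x, obs, c(1L, 1L), refs[2, , drop = FALSE], blocks2)
  expect_equal(unname(out1[c("b1", "b2")]), c(20, 21))
  expect_error(refine_to_profile(x, obs, c(1L, 1L),
                                 refs[integer(0), , drop = FALSE], blocks2),
               "empty reference")
})

test_that("weighted-average refinement pools the m nearest references", {
  refs <- rbind(c(0.0, 0.0, 10, 100),
                c(0.3, 0.4, 20, 200),
                c(5.0, 5.0, 30, 300))
  colnames(refs) <- c("a1", "a2", "b1", "b2")
  x <- c(a1 = 0, a2 = 0, b1 = NA, b2 = NA)
  obs <- c(TRUE, TRUE, FALSE, FALSE)
  out <- refine_to_profile(x, obs, c(1L, 1L), refs, blocks2,
                           imputer_config(refine_mode = "weighted_average", m = 2))
  # ref1 at distance 0 dominates by the exact-duplicate rule
  expect_equal(unname(out[c("b1", "b2")]), c(10, 100))
  x2 <- c(a1 = 0.1, a2 = 0.1, b1 = NA, b2 = NA)
  out2 <- refine_to_profile(x2, obs, c(1L, 1L), refs, blocks2,
                            imputer_config(refine_mode = "weighted_average", m = 2))
  d <- c(sqrt(2 * 0.01), sqrt(0.04 + 0.09))
  w <- (1 / d) / sum(1 / d)
  expect_equal(unname(out2["b1"]), sum(w * c(10, 20)))
})

test_that("refinement never touches features outside the required blocks", {
  refs <- matrix(runif(8), 2, 4, dimnames = list(NULL, c("a1", "a2", "b1", "b2")))
  x <- c(a1 = NA, a2 = NA, b1 = 0.5, b2 = 0.6)
  obs <- c(FALSE, FALSE, TRUE, TRUE)
  # target requires only block B (already observed): nothing changes
  expect_identical(refine_to_profile(x, obs, c(0L, 1L), refs, blocks2), x)
  # target requires block A: block B stays untouched
  out <- refine_to_profile(x, obs, c(1L, 1L), refs, blocks2)
  expect_identical(out[c("b1", "b2")], x[c("b1", "b2")])
  expect_false(anyNA(out[c("a1", "a2")]))
})

test_that("two-step test imputation equals composing the steps", {
  withr::with_seed(31, {
    train <- matrix(runif(24), 6, 4, dimnames = list(NULL, c("a1", "a2", "b1", "b2")))
    train[2, 3:4] <- NA  # one incomplete donor
    refs <- train[complete.cases(train), , drop = FALSE]
    x <- c(a1 = 0.4, a2 = 0.6, b1 = NA, b2 = NA)
    cfg <- imputer_config(k = 3)
    got <- two_step_test_impute(x, c(1L, 1L), train, refs, blocks2, cfg)
    step1 <- knn_impute(x, train, cfg)[1, ]
    want <- refine_to_profile(step1, !is.na(x), c(1L, 1L), refs, blocks2, cfg)
    expect_identical(got, want)
    expect_false(anyNA(got))
    # complete sample: both steps are the identity on its scope
    full <- c(a1 = 0.1, a2 = 0.2, b1 = 0.3, b2 = 0.4)
    expect_identical(two_step_test_impute(full, c(1L, 1L), train, refs,
                                          blocks2, cfg), full)
  })
})
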