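#' Fit a missing-data handling strategy
#'
#' Four strategies share one per-subset pipeline (restrict to the subset's
#' blocks, fit a min-max scaler, oversample the minority class, train one
#' classifier):
#'
#' * `dynamic` — available-case ensemble with one model per missingness
#'   profile observed in training; unseen test profiles trigger on-demand
#'   training from the training set's containment subset (cached).
#' * `exhaustive` — one model per possible non-zero profile (`2^S - 1`)
#'   whose containment subset is non-empty, so every pattern is pre-covered.
#' * `imputation` — the whole training matrix is completed by
#'   distance-weighted KNN and a single full-scope model is trained; test
#'   samples are two-step imputed individually against the completed pool.
#' * `hybrid` — trains like `dynamic`, but unseen test profiles are routed
#'   by Hamming distance to compatible pre-trained models, with selective
#'   test-time imputation and majority voting; no retraining ever.
#'
#' @param train a labelled [multiomics_dataset()] with block-constant
#'   per-sample masks
#' @param kind `"dynamic"`, `"exhaustive"`, `"imputation"` or `"hybrid"`
#' @param spec a [classifier_spec()]
#' @param imputer an [imputer_config()]
#' @param seed integer master seed; per-subset oversampling and model fits
#'   draw independent derived streams keyed by profile code only, so
#'   strategies sharing a profile fit identical models
#' @return object of class `blockhybrid_ensemble`
#' @export
fit_strategy <- function(train, kind = c("dynamic", "exhaustive",
                                         "imputation", "hybrid"),
                         spec = classifier_spec(), imputer = imputer_config(),
                         seed = 1L) {
  kind <- match.arg(kind)
  if (is.null(train$labels)) stop("training labels required")
  codes <- profile_codes(train)
  S <- n_blocks(train)
  obs_any <- colSums(train$mask) > 0L
  raw <- masked_values(train)
  global_scaler <- minmax_fit(raw[, obs_any, drop = FALSE])

  ens <- structure(
    list(kind = kind, S = S, blocks = block_feature_list(train),
         spec = spec, imputer = imputer, seed = seed,
         sample_codes = codes, global_scaler = global_scaler,
         obs_features = colnames(raw)[obs_any],
         cache = new.env(parent = emptyenv())),
    class = "blockhybrid_ensemble")

  if (kind == "imputation") {
    if (!all(obs_any)) {
      stop("imputation strategy requires every feature observed in >= 1 ",
           "training sample; unobserved: ",
           paste(head(colnames(raw)[!obs_any], 5), collapse = ", "))
    }
    norm <- minmax_apply(global_scaler, raw)
    completed_norm <- knn_impute(norm, norm, imputer)
    completed_raw <- minmax_invert(global_scaler, completed_norm)
    colnames(completed_raw) <- colnames(raw)
    full_code <- to_decimal(rep(1L, S))
    model <- fit_subset_model(completed_raw, train$labels, colnames(raw),
                              full_code, nrow(completed_raw), spec, seed)
    ens$models <- setNames(list(model), as.character(full_code))
    ens$completed_pool <- completed_raw
  } else {
    keys <- if (kind == "exhaustive") seq_len(2^S - 1L) else NULL
    subsets <- build_subsets(codes, S, keys = keys)
    if (length(subsets) == 0L) stop("zero trainable subsets")
    ens$models <- lapply(names(subsets), function(q) {
      train_profile_model(train, as.integer(q), subsets[[q]], spec, seed)
    })
    names(ens$models) <- names(subsets)
  }
  ens$train <- train
  # normalized imputation space, cached for test-time routing
  ens$train_norm <- minmax_apply(global_scaler, raw[, obs_any, drop = FALSE])
  if (kind == "imputation") {
    ens$completed_pool_norm <- minmax_apply(global_scaler, ens$completed_pool)
  }
  ens$trained_codes <- as.integer(names(ens$models))
  ens$subset_sizes <- vapply(ens$models, `[[`, numeric(1), "n_subset")
  ens
}

#' @export
print.blockhybrid_ensemble <- function(x, ...) {
  cat(sprintf("blockhybrid_ensemble (%s): %d model(s) over %d blocks\n",
              x$kind, length(x$models), x$S))
  cat("  profiles:", paste(names(x$models), collapse = ", "), "\n")
  invisible(x)
}

# shared per-subset pipeline: scale -> oversample -> train
fit_subset_model <- function(X_raw, y, feats, code, n_subset, spec, seed) {
  scaler <- minmax_fit(X_raw)
  Xn <- minmax_apply(scaler, X_raw)
  if (length(unique(y)) > 1L) {
    bal <- oversample_minority(Xn, y, derive_seed(seed, paste0("oversample:", code)))
    Xn <- bal$features; y <- bal$labels
  }
  model <- train_classifier(Xn, y, spec, derive_seed(seed, paste0("fit:", code)))
  list(model = model, scaler = scaler, code = code, feats = feats,
       n_subset = n_subset)
}

train_profile_model <- function(train, code, members, spec, seed) {
  bits <- from_decimal(code, n_blocks(train))
  feats <- block_features(train, names(train$blocks)[bits == 1L])
  X <- masked_values(train)[members, feats, drop = FALSE]
  fit_subset_model(X, train$labels[members], feats, code, length(members),
                   spec, seed)
}

#' Route a test profile to compatible trained models
#'
#' Exact match wins outright. Otherwise all superset-compatible trained
#' profiles (models that consume every observed block of the sample) at
#' minimal Hamming distance are selected for test-time imputation. If none
#' exists, strict-subset profiles at minimal Hamming distance (maximal
#' shared omics) are used without imputation.
#'
#' @param test_code integer profile code of the test sample
#' @param trained_codes integer codes of the trained models
#' @param S number of blocks
#' @return object of class `routing_decision`: list with `mode` (`exact`,
#'   `impute_superset` or `subset_fallback`), `candidates` (codes,
#'   ascending) and `distance`
#' @export
route_hybrid <- function(test_code, trained_codes, S) {
  if (length(trained_codes) == 0L) stop("no trained profiles to route to")
  test_code <- as.integer(test_code)
  trained_codes <- sort(as.integer(trained_codes))
  decision <- function(mode, candidates, distance = NA_integer_) {
    structure(list(mode = mode, candidates = candidates,
                   distance = distance), class = "routing_decision")
  }
  if (test_code %in% trained_codes) {
    return(decision("exact", test_code, 0L))
  }
  tb <- from_decimal(test_code, S)
  dists <- vapply(trained_codes, function(cand)
    hamming(tb, from_decimal(cand, S)), integer(1))
  super <- vapply(trained_codes, function(cand)
    is_superset_compatible(tb, from_decimal(cand, S)), logical(1))
  if (any(super)) {
    dmin <- min(dists[super])
    return(decision("impute_superset",
                    trained_codes[super & dists == dmin], dmin))
  }
  sub <- vapply(trained_codes, function(cand)
    is_superset_compatible(from_decimal(cand, S), tb), logical(1))
  if (any(sub)) {
    dmin <- min(dists[sub])
    return(decision("subset_fallback",
                    trained_codes[sub & dists == dmin], dmin))
  }
  stop("no superset- or subset-compatible trained profile for test profile ",
       paste(tb, collapse = ""), "; train a model covering at least one of ",
       "its blocks alone, or use the dynamic strategy")
}

#' @export
print.routing_decision <- function(x, ...) {
  cat(sprintf("routing: %s -> {%s} (Hamming %s)\n", x$mode,
              paste(x$candidates, collapse = ", "), x$distance))
  invisible(x)
}

#' Majority vote over candidate predictions
#'
#' Strict majority wins. Even splits go to the vote of the candidate with
#' the largest training subset, then to the smallest profile code. The
#' consensus tie-break ([consensus_tiebreak()]) is an optional alternative
#' wired in by the hybrid predictor when `tie_policy = "consensus"`.
#'
#' @param votes integer 0/1 votes, one per candidate
#' @param subset_sizes training-subset sizes, aligned with `votes`
#' @param codes candidate profile codes, aligned with `votes`
#' @return the winning 0/1 label
#' @export
majority_vote <- function(votes, subset_sizes = NULL, codes = NULL) {
  if (length(votes) == 0L) stop("empty vote list")
  n1 <- sum(votes == 1L); n0 <- sum(votes == 0L)
  if (n1 != n0) return(as.integer(n1 > n0))
  subset_sizes <- subset_sizes %||% rep(1, length(votes))
  codes <- codes %||% seq_along(votes)
  ord <- order(-subset_sizes, codes)
  as.integer(votes[ord[1]])
}

#' Consensus tie-break across imputed versions
#'
#' Averages the candidate-specific imputed versions of one sample into a
#' consensus vector, maps it to the trained profile whose training-subset
#' centroid is nearest (Euclidean over that profile's feature scope, ties
#' to the smallest code), and returns that model's prediction on the
#' consensus. Off by default; the primary pipeline resolves ties by
#' training-subset size.
#'
#' @param imputed_versions matrix of `>= 2` imputed versions of one sample
#'   (rows) on the common full feature scope, raw scale
#' @param ensemble a fitted `blockhybrid_ensemble`
#' @return 0/1 label
#' @export
consensus_tiebreak <- function(imputed_versions, ensemble) {
  imputed_versions <- rbind(imputed_versions)
  if (nrow(imputed_versions) < 2L) stop("need >= 2 imputed versions")
  consensus <- colMeans(imputed_versions)
  names(consensus) <- colnames(imputed_versions)
  raw <- masked_values(ensemble$train)
  codes <- ensemble$sample_codes
  best <- NULL
  for (q in ensemble$trained_codes) {
    m <- ensemble$models[[as.character(q)]]
    members <- which(bitwAnd(codes, q) == q)
    centroid <- colMeans(raw[members, m$feats, drop = FALSE])
    d <- sqrt(sum((consensus[m$feats] - centroid)^2))
    if (is.null(best) || d < best$d) best <- list(q = q, d = d)
  }
  model_predict(ensemble, best$q, consensus)
}

# normalize a raw-scale row with a subset model's own scaler and predict
model_predict <- function(ens, code, raw_row) {
  m <- ens$models[[as.character(code)]]
  x <- rbind(raw_row[m$feats])
  colnames(x) <- m$feats
  predict_label(m$model, minmax_apply(m$scaler, x))
}

# two-step impute a raw test row toward a target profile, in the globally
# normalized imputation space; returns the full-length raw-scale row with
# the required blocks filled
impute_toward <- function(ens, target_code, raw_row, observed) {
  feats <- ens$obs_features
  train_norm <- ens$train_norm
  row_norm <- minmax_apply(ens$global_scaler, rbind(raw_row[feats]))[1, ]
  names(row_norm) <- feats
  bits <- from_decimal(target_code, ens$S)
  target_feats <- unlist(ens$blocks[bits == 1L], use.names = FALSE)
  blocks_obs <- lapply(ens$blocks, function(f) intersect(f, feats))
  # step 1: global KNN completion, confined to the target scope
  fill <- intersect(target_feats, feats)
  step1 <- knn_impute_fill(row_norm, train_norm, ens$imputer, fill)
  # step 2: refinement from the target profile's training subset
  members <- which(bitwAnd(ens$sample_codes, target_code) == target_code)
  refined <- refine_to_profile(
    step1, observed[feats], bits,
    train_norm[members, , drop = FALSE], blocks_obs, ens$imputer)
  out_norm <- minmax_invert(ens$global_scaler, rbind(refined))[1, ]
  out <- raw_row
  out[feats] <- out_norm
  out[observed] <- raw_row[observed]
  out
}

# knn_impute restricted to filling a feature subset
knn_impute_fill <- function(row_norm, donors, config, fill) {
  miss <- names(row_norm)[is.na(row_norm)]
  dist <- nan_euclidean(row_norm, donors)
  out <- row_norm
  for (j in intersect(miss, fill)) {
    val <- knn_fill_value(dist, donors[, j], config$k)
    if (is.na(val)) val <- mean(donors[, j], na.rm = TRUE)
    out[j] <- val
  }
  out
}

#' Predict with a fitted strategy
#'
#' @param ensemble a [fit_strategy()] result
#' @param test a [multiomics_dataset()] with block-constant per-sample masks
#' @param tie_policy `"largest_subset"` (default) or `"consensus"`
#'   (hybrid-only optional extension, see [consensus_tiebreak()])
#' @return list with `labels` (integer 0/1 per test sample) and `audit`
#'   (data.frame: sample id, profile bits and code, routing mode, candidate
#'   codes, per-candidate votes, final label, and for the dynamic strategy
#'   whether a new model was trained for this sample)
#' @export
predict_strategy <- function(ensemble, test,
                             tie_policy = c("largest_subset", "consensus")) {
  tie_policy <- match.arg(tie_policy)
  n <- n_samples(test)
  raw <- masked_values(test)
  labels <- integer(n)
  audit <- vector("list", n)
  for (i in seq_len(n)) {
    res <- tryCatch(
      predict_one(ensemble, raw[i, ], test$mask[i, ], tie_policy),
      error = function(e) stop("sample ", test$sample_ids[i], ": ",
                               conditionMessage(e), call. = FALSE))
    labels[i] <- res$label
    audit[[i]] <- data.frame(
      sample_id = test$sample_ids[i], profile_code = res$code,
      mode = res$mode,
      candidates = paste(res$candidates, collapse = "+"),
      votes = paste(res$votes, collapse = "+"),
      label = res$label, trained_new = res$trained_new,
      stringsAsFactors = FALSE)
  }
  list(labels = labels, audit = do.call(rbind, audit))
}

predict_one <- function(ens, raw_row, mask_row, tie_policy) {
  code <- profile_of(mask_row, ens$blocks)$code
  out <- list(code = code, trained_new = FALSE)
  exact_predict <- function(q) {
    out$mode <<- "exact"; out$candidates <<- q
    out$votes <<- model_predict(ens, q, raw_row)
    out$label <<- out$votes
  }
  fallback_predict <- function() {
    route <- route_hybrid(code, ens$trained_codes, ens$S)
    if (route$mode != "subset_fallback") {
      stop("no exact or subset-compatible model for profile code ", code)
    }
    votes <- vapply(route$candidates, function(q)
      model_predict(ens, q, raw_row), integer(1))
    out$mode <<- "subset_fallback"; out$candidates <<- route$candidates
    out$votes <<- votes
    out$label <<- majority_vote(votes,
                                ens$subset_sizes[as.character(route$candidates)],
                                route$candidates)
  }
  switch(ens$kind,
    dynamic = {
      key <- as.character(code)
      if (code %in% ens$trained_codes) {
        exact_predict(code)
      } else if (!is.null(ens$cache[[key]])) {
        m <- ens$cache[[key]]
        out$mode <- "retrain"; out$candidates <- code
        x <- rbind(raw_row[m$feats]); colnames(x) <- m$feats
        out$votes <- predict_label(m$model, minmax_apply(m$scaler, x))
        out$label <- out$votes
      } else {
        members <- which(bitwAnd(ens$sample_codes, code) == code)
        if (length(members) == 0L) {
          fallback_predict()
        } else {
          m <- train_profile_model(ens$train, code, members, ens$spec,
                                   ens$seed)
          ens$cache[[key]] <- m
          out$mode <- "retrain"; out$candidates <- code
          out$trained_new <- TRUE
          x <- rbind(raw_row[m$feats]); colnames(x) <- m$feats
          out$votes <- predict_label(m$model, minmax_apply(m$scaler, x))
          out$label <- out$votes
        }
      }
    },
    exhaustive = {
      if (code %in% ens$trained_codes) exact_predict(code)
      else fallback_predict()
    },
    imputation = {
      full_code <- to_decimal(rep(1L, ens$S))
      norm_pool <- ens$completed_pool_norm
      row_norm <- minmax_apply(ens$global_scaler, rbind(raw_row))[1, ]
      names(row_norm) <- colnames(ens$completed_pool)
      step1 <- knn_impute(row_norm, norm_pool, ens$imputer)[1, ]
      refined <- refine_to_profile(step1, mask_row, rep(1L, ens$S),
                                   norm_pool, ens$blocks, ens$imputer)
      completed_raw <- minmax_invert(ens$global_scaler, rbind(refined))[1, ]
      names(completed_raw) <- colnames(ens$completed_pool)
      completed_raw[mask_row] <- raw_row[mask_row]
      out$mode <- "imputed"; out$candidates <- full_code
      out$votes <- model_predict(ens, full_code, completed_raw)
      out$label <- out$votes
    },
    hybrid = {
      route <- route_hybrid(code, ens$trained_codes, ens$S)
      out$mode <- route$mode
      out$candidates <- route$candidates
      if (route$mode == "exact") {
        out$votes <- model_predict(ens, code, raw_row)
        out$label <- out$votes
      } else if (route$mode == "impute_superset") {
        versions <- lapply(route$candidates, function(q)
          impute_toward(ens, q, raw_row, mask_row))
        votes <- vapply(seq_along(route$candidates), function(k)
          model_predict(ens, route$candidates[k], versions[[k]]), integer(1))
        out$votes <- votes
        n1 <- sum(votes == 1L)
        if (tie_policy == "consensus" && n1 * 2L == length(votes)) {
          out$label <- consensus_tiebreak(do.call(rbind, versions), ens)
        } else {
          out$label <- majority_vote(
            votes, ens$subset_sizes[as.character(route$candidates)],
            route$candidates)
        }
      } else {
        votes <- vapply(route$candidates, function(q)
          model_predict(ens, q, raw_row), integer(1))
        out$votes <- votes
        out$label <- majority_vote(
          votes, ens$subset_sizes[as.character(route$candidates)],
          route$candidates)
      }
    })
  out
}
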