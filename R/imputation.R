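#' Configuration for the two-step KNN imputer
#'
#' @param k neighbour count for the global distance-weighted completion
#'   (default 10)
#' @param refine_mode test-time refinement: `"single_nearest"` copies each
#'   required missing block wholesale from the nearest profile-compatible
#'   reference (the default, preserving observed block coherence);
#'   `"weighted_average"` fills them by inverse-distance-weighted
#'   aggregation over the `m` nearest references
#' @param m donor count for `weighted_average` (default `k`)
#' @return object of class `imputer_config`
#' @export
imputer_config <- function(k = 10L,
                           refine_mode = c("single_nearest", "weighted_average"),
                           m = k) {
  refine_mode <- match.arg(refine_mode)
  if (k < 1L) stop("k must be >= 1")
  if (m < 1L) stop("m must be >= 1")
  structure(list(k = as.integer(k), refine_mode = refine_mode,
                 m = as.integer(m), weighting = "inverse_distance"),
            class = "imputer_config")
}

# Euclidean distance over mutually observed coordinates, rescaled by
# sqrt(d_total / d_shared) so partially observed pairs stay comparable.
# Rows with no shared coordinate get Inf.
nan_euclidean <- function(query, donors) {
  d_total <- length(query)
  shared <- !is.na(donors) & matrix(rep(!is.na(query), each = nrow(donors)),
                                    nrow = nrow(donors))
  diff2 <- (donors - matrix(rep(query, each = nrow(donors)),
                            nrow = nrow(donors)))^2
  diff2[!shared] <- 0
  n_shared <- rowSums(shared)
  d2 <- rowSums(diff2)
  out <- sqrt(d_total / n_shared * d2)
  out[n_shared == 0L] <- Inf
  out
}

# Weighted mean over the k nearest candidate donors with the feature
# observed. Zero-distance donors dominate by the exact-duplicate rule:
# unweighted mean over them, never infinite weights.
knn_fill_value <- function(dist, donor_vals, k) {
  ok <- which(!is.na(donor_vals) & is.finite(dist))
  if (length(ok) == 0L) return(NA_real_)
  ord <- ok[order(dist[ok], ok)]
  sel <- ord[seq_len(min(k, length(ord)))]
  d <- dist[sel]
  if (any(d == 0)) {
    return(mean(donor_vals[sel[d == 0]]))
  }
  w <- 1 / d
  sum(w * donor_vals[sel]) / sum(w)
}

#' Distance-weighted K-nearest-neighbour completion
#'
#' Fills every missing cell of `x` with the inverse-distance-weighted mean
#' of the `k` nearest donors' observed values for that feature. Similarity
#' is Euclidean distance over mutually observed coordinates, rescaled by
#' `sqrt(d_total / d_shared)`; donors at distance zero contribute an
#' unweighted mean. Inputs are expected min-max normalized on a shared fit
#' so all features weigh equally in the distance.
#'
#' @param x numeric matrix (or single row) with `NA` for missing cells
#' @param donors numeric donor matrix, possibly itself incomplete
#' @param config an [imputer_config()]
#' @param fallback_mean when a feature is observed in no donor, fill with
#'   the donor-pool feature mean and warn (`TRUE`, default) or error
#' @return `x` with every `NA` replaced; observed cells bit-identical
#' @export
knn_impute <- function(x, donors, config = imputer_config(),
                       fallback_mean = TRUE) {
  x <- rbind(x)  # promote single sample to 1-row matrix
  donors <- as.matrix(donors)
  if (ncol(x) != ncol(donors)) stop("feature dimension mismatch")
  out <- x
  col_obs <- colSums(!is.na(donors))
  for (i in seq_len(nrow(x))) {
    miss <- which(is.na(x[i, ]))
    if (length(miss) == 0L) next
    if (all(is.na(x[i, ]))) stop("sample ", i, " has no observed feature")
    dist <- nan_euclidean(x[i, ], donors)
    for (j in miss) {
      val <- knn_fill_value(dist, donors[, j], config$k)
      if (is.na(val)) {
        if (col_obs[j] == 0L || !fallback_mean) {
          stop("feature ", colnames(donors)[j] %||% j,
               " observed in no ", if (col_obs[j] == 0L) "donor"
               else "reachable donor (fallback disabled)")
        }
        # donors with the feature exist but share no coordinate with the
        # query; fall back to the donor-pool feature mean
        warning("no reachable donor for feature ",
                colnames(donors)[j] %||% j, "; using donor-pool mean")
        val <- mean(donors[, j], na.rm = TRUE)
      }
      out[i, j] <- val
    }
  }
  out
}

#' Refine a test sample toward a target profile from compatible references
#'
#' Second imputation step, applied at test time: donor similarity is
#' Euclidean distance computed ONLY over the test sample's originally
#' observed features, and only the blocks missing in the test sample but
#' required by the target profile are replaced. Under `single_nearest` they
#' are copied wholesale from the one nearest reference (ties broken by
#' lowest reference index); under `weighted_average` they are
#' inverse-distance-weighted means over the `m` nearest references.
#'
#' @param test_values numeric vector: the test sample (step-1 completed or
#'   raw; only its originally observed features enter the distance)
#' @param test_observed logical vector: the sample's ORIGINAL observation
#'   mask
#' @param target_bits 0/1 vector: the target model's profile
#' @param reference_values matrix of training samples fully observed on the
#'   target profile's blocks
#' @param blocks named list of feature-id vectors defining block membership
#'   (features ordered block by block, matching `test_values`)
#' @param config an [imputer_config()]
#' @return the refined sample vector; originally observed values untouched,
#'   and features outside (target blocks minus observed blocks) untouched
#' @export
refine_to_profile <- function(test_values, test_observed, target_bits,
                              reference_values, blocks,
                              config = imputer_config()) {
  if (nrow(rbind(reference_values)) == 0L) {
    stop("empty reference subset; the router must pick another candidate")
  }
  reference_values <- rbind(reference_values)
  if (!any(test_observed)) stop("test sample has no observed feature")
  target_bits <- as.integer(target_bits)
  feats <- unlist(blocks, use.names = FALSE)
  block_of <- rep(seq_along(blocks), lengths(blocks))
  # blocks missing in the test sample (no observed feature) but required
  block_missing <- vapply(seq_along(blocks),
                          function(b) !any(test_observed[block_of == b]),
                          logical(1))
  to_fill <- which(block_missing & target_bits == 1L)
  out <- test_values
  if (length(to_fill) == 0L) return(out)
  scope <- which(test_observed)
  dist <- nan_euclidean(test_values[scope],
                        reference_values[, scope, drop = FALSE])
  fill_cols <- which(block_of %in% to_fill)
  if (config$refine_mode == "single_nearest") {
    best <- which(dist == min(dist))[1]  # lowest index on ties
    out[fill_cols] <- reference_values[best, fill_cols]
  } else {
    ord <- order(dist, seq_along(dist))
    sel <- ord[seq_len(min(config$m, length(ord)))]
    d <- dist[sel]
    if (any(d == 0)) {
      sel <- sel[d == 0]
      out[fill_cols] <- colMeans(reference_values[sel, fill_cols, drop = FALSE])
    } else {
      w <- 1 / d
      out[fill_cols] <- colSums(reference_values[sel, fill_cols, drop = FALSE] * w) / sum(w)
    }
  }
  out
}

#' Two-step test-time imputation toward a target profile
#'
#' Step 1: global distance-weighted KNN completion of the sample against the
#' full training matrix. Step 2: profile refinement via
#' [refine_to_profile()] using the training samples fully observed on the
#' target profile's blocks. The result, restricted to the target profile's
#' feature scope, is fully observed.
#'
#' @param test_values numeric vector with `NA` for missing cells
#' @param test_observed logical original observation mask (defaults to
#'   `!is.na(test_values)`)
#' @param target_bits 0/1 target profile
#' @param train_values training matrix (donor pool), `NA` for missing
#' @param reference_values training samples fully observed on the target
#'   blocks (step-2 donors)
#' @param blocks named list of feature-id vectors
#' @param config an [imputer_config()]
#' @return completed sample vector
#' @export
two_step_test_impute <- function(test_values, target_bits, train_values,
                                 reference_values, blocks,
                                 config = imputer_config(),
                                 test_observed = !is.na(test_values)) {
  step1 <- knn_impute(test_values, train_values, config)[1, ]
  refine_to_profile(step1, test_observed, target_bits, reference_values,
                    blocks, config)
}
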