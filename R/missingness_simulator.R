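#' Scenario configurations for block-wise missingness injection
#'
#' A scenario configuration names the availability patterns injected into
#' the training and testing sides and the fraction of samples receiving each
#' pattern. Under the default `complete` remainder policy the remaining
#' samples stay fully observed; under `renormalize` the fractions are
#' rescaled to sum to 1 so every sample receives a listed pattern.
#'
#' @param scenario one of `same_patterns`, `light_generalization`,
#'   `high_generalization`, `missing_omic`, `sparse_train_rich_test`
#' @param config_id integer 1..3
#' @param train_assignments,test_assignments lists of
#'   `list(pattern = <bitstring>, fraction = <prop>)`
#' @param remainder_policy `"complete"` or `"renormalize"`
#' @return object of class `scenario_config`
#' @export
scenario_config <- function(scenario, config_id, train_assignments,
                            test_assignments,
                            remainder_policy = c("complete", "renormalize")) {
  remainder_policy <- match.arg(remainder_policy)
  norm <- function(a) {
    lapply(a, function(x) list(pattern = as.character(x$pattern),
                               fraction = as.numeric(x$fraction)))
  }
  structure(
    list(scenario = scenario, config_id = as.integer(config_id),
         train_assignments = norm(train_assignments),
         test_assignments = norm(test_assignments),
         remainder_policy = remainder_policy),
    class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  fmt <- function(a) paste(vapply(a, function(p)
    sprintf("%s@%.3g", p$pattern, p$fraction), character(1)), collapse = ", ")
  cat(sprintf("%s config %d (%s remainder)\n  train: %s\n  test:  %s\n",
              x$scenario, x$config_id, x$remainder_policy,
              fmt(x$train_assignments), fmt(x$test_assignments)))
  invisible(x)
}

assignment <- function(pattern, fraction) list(pattern = pattern, fraction = fraction)

make_assignments <- function(patterns, fractions) {
  mapply(assignment, patterns, fractions, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' The fifteen built-in train/test missingness configurations
#'
#' Five scenarios (same patterns; light and high generalization; missing
#' omic; sparse training / rich testing), three configurations each, over
#' four blocks in the fixed order `[rs, cn, mu, pp]`. Pattern bitstrings and
#' fractions follow the study design this package reimplements; the largest
#' summed pattern fraction across all lists is 0.60.
#'
#' @param remainder_policy applied to every returned config
#' @return list of 15 [scenario_config()] objects
#' @export
builtin_configs <- function(remainder_policy = c("complete", "renormalize")) {
  remainder_policy <- match.arg(remainder_policy)
  cfg <- function(scen, id, trp, trf, tep, tef) {
    scenario_config(scen, id, make_assignments(trp, trf),
                    make_assignments(tep, tef), remainder_policy)
  }
  list(
    cfg("same_patterns", 1,
        c("1101", "0111", "1011", "0110"), c(.10, .10, .10, .10),
        c("1101", "0111", "1011", "0110"), c(.10, .10, .10, .10)),
    cfg("same_patterns", 2,
        c("1110", "0110", "1011", "1001"), c(.10, .10, .10, .10),
        c("1110", "0110", "1011", "1001"), c(.10, .10, .10, .10)),
    cfg("same_patterns", 3,
        c("1110", "1011", "0001", "0111"), c(.10, .10, .05, .10),
        c("1110", "1011", "0001", "0111"), c(.10, .10, .025, .10)),
    cfg("light_generalization", 1,
        c("1011", "0111", "1101", "0110"), c(.10, .10, .10, .10),
        c("1101", "0101", "0111", "1011"), c(.10, .10, .10, .10)),
    cfg("light_generalization", 2,
        c("1110", "1101", "0111"), c(.10, .10, .10),
        c("1101", "0111", "1010", "0101"), c(.10, .10, .10, .10)),
    cfg("light_generalization", 3,
        c("0101", "1011", "1100", "0001"), c(.10, .10, .10, .05),
        c("0101", "1011", "1010"), c(.10, .10, .20)),
    cfg("high_generalization", 1,
        c("1110", "0111", "1011", "1101"), c(.15, .15, .10, .10),
        c("0001", "0010", "0100", "1010", "0011", "1001"),
        c(.10, .05, .05, .10, .10, .10)),
    cfg("high_generalization", 2,
        c("1001", "0111", "1010", "0001"), c(.10, .10, .10, .10),
        c("0011", "0010", "0101", "1110"), c(.10, .10, .10, .10)),
    cfg("high_generalization", 3,
        c("1110", "1101", "1011", "0101"), c(.10, .10, .10, .10),
        c("1001", "1110", "0011", "1010", "1101", "0110"),
        c(.10, .10, .10, .10, .10, .10)),
    cfg("missing_omic", 1,
        c("0011", "1011", "0111"), c(.10, .10, .10),
        c("1110", "0110", "1010"), c(.05, .05, .05)),
    cfg("missing_omic", 2,
        c("1010", "1011", "0111", "0010"), c(.10, .10, .10, .10),
        c("1101", "1100"), c(.15, .15)),
    cfg("missing_omic", 3,
        c("0100", "1110", "0101", "1100"), c(.10, .10, .10, .10),
        c("1011", "1010", "1001", "1000"), c(.10, .10, .05, .05)),
    cfg("sparse_train_rich_test", 1,
        c("0001", "0010", "1001", "1000"), c(.10, .10, .10, .10),
        c("1110", "0111"), c(.15, .15)),
    cfg("sparse_train_rich_test", 2,
        c("0001", "0100", "1000", "0110"), c(.10, .10, .10, .15),
        c("1011", "1110", "0111"), c(.15, .15, .15)),
    cfg("sparse_train_rich_test", 3,
        c("0010", "0100", "0001", "1010"), c(.10, .10, .10, .20),
        c("1101", "1110"), c(.20, .20))
  )
}

#' Validate a scenario configuration
#'
#' @param config a [scenario_config()]
#' @return character vector of findings; empty when valid
#' @export
validate_config <- function(config) {
  findings <- character(0)
  check_side <- function(assignments, side) {
    pats <- vapply(assignments, `[[`, character(1), "pattern")
    fracs <- vapply(assignments, `[[`, numeric(1), "fraction")
    if (any(grepl("^0+$", pats))) {
      findings <<- c(findings, sprintf("%s: all-zero pattern", side))
    }
    if (any(!grepl("^[01]+$", pats))) {
      findings <<- c(findings, sprintf("%s: pattern not a 0/1 bitstring", side))
    }
    if (anyDuplicated(pats)) {
      findings <<- c(findings, sprintf("%s: duplicate pattern", side))
    }
    if (length(unique(nchar(pats))) > 1L) {
      findings <<- c(findings, sprintf("%s: patterns of unequal length", side))
    }
    bad <- fracs <= 0 | fracs > 1
    if (any(bad)) {
      findings <<- c(findings,
                     sprintf("%s: fraction outside (0, 1]: %s", side,
                             paste(fracs[bad], collapse = ", ")))
    }
    if (config$remainder_policy == "complete" && sum(fracs) > 1 + 1e-12) {
      findings <<- c(findings,
                     sprintf("%s: fractions sum to %.4g > 1 under complete policy",
                             side, sum(fracs)))
    }
  }
  check_side(config$train_assignments, "train")
  check_side(config$test_assignments, "test")
  findings
}

# largest-remainder apportionment of counts for the assignments
assignment_counts <- function(fractions, n, policy) {
  if (policy == "renormalize") {
    f <- fractions / sum(fractions)
    base <- floor(n * f)
    rem <- n * f - base
    deficit <- n - sum(base)
    if (deficit > 0) {
      take <- order(rem, decreasing = TRUE)[seq_len(deficit)]
      base[take] <- base[take] + 1
    }
    return(as.integer(base))
  }
  ideal <- n * fractions
  counts <- as.integer(round_half_away(ideal))
  excess <- sum(counts) - n
  while (excess > 0) {
    # withdraw from the pattern whose rounding gained it the most
    gain <- counts - ideal
    i <- which.max(gain)
    counts[i] <- counts[i] - 1L
    excess <- excess - 1L
  }
  counts
}

#' Inject block-wise missingness into a complete dataset
#'
#' Each assignment's pattern is applied to `round(n * fraction)` samples
#' (half away from zero, reconciled by largest remainder so counts never
#' exceed `n`), chosen without replacement via `seed`; every block with a 0
#' bit in the pattern is masked for those samples. Values under the mask are
#' hidden, not altered, so un-masking reproduces the input exactly.
#'
#' @param ds a complete [multiomics_dataset()] (all cells observed)
#' @param assignments list of `list(pattern, fraction)` (bitstrings over the
#'   dataset's blocks); an empty list returns `ds` unchanged
#' @param seed integer seed
#' @param remainder_policy `"complete"` leaves unassigned samples fully
#'   observed; `"renormalize"` rescales fractions to sum to 1 so every
#'   sample receives a listed pattern
#' @return the dataset with an updated mask (block-constant per sample)
#' @export
inject_missingness <- function(ds, assignments, seed,
                               remainder_policy = c("complete", "renormalize")) {
  remainder_policy <- match.arg(remainder_policy)
  if (!all(ds$mask)) stop("inject_missingness requires a complete dataset")
  if (length(assignments) == 0L) return(ds)
  S <- n_blocks(ds)
  pats <- vapply(assignments, `[[`, character(1), "pattern")
  if (any(nchar(pats) != S)) {
    stop("pattern bit length must equal the number of blocks (", S, ")")
  }
  fracs <- vapply(assignments, `[[`, numeric(1), "fraction")
  n <- n_samples(ds)
  counts <- assignment_counts(fracs, n, remainder_policy)
  order_idx <- withr::with_seed(seed, sample.int(n))
  mask <- ds$mask
  feats_of_block <- block_feature_list(ds)
  taken <- 0L
  for (k in seq_along(assignments)) {
    if (counts[k] == 0L) next
    rows <- order_idx[(taken + 1L):(taken + counts[k])]
    taken <- taken + counts[k]
    bits <- as.integer(strsplit(pats[k], "")[[1]])
    for (b in which(bits == 0L)) {
      mask[rows, feats_of_block[[b]]] <- FALSE
    }
  }
  out <- ds
  out$mask <- mask
  out
}

#' Maximum summed pattern fraction across configurations
#'
#' The largest total proportion of samples assigned a missingness pattern in
#' any train or test assignment list — the headline "up to X% block-wise
#' missingness" of a scenario battery. For the built-in configurations this
#' is 0.60.
#'
#' @param configs list of [scenario_config()]
#' @return numeric proportion
#' @export
max_missingness_fraction <- function(configs) {
  if (length(configs) == 0L) stop("non-empty config list required")
  sums <- unlist(lapply(configs, function(cf) {
    c(sum(vapply(cf$train_assignments, `[[`, numeric(1), "fraction")),
      sum(vapply(cf$test_assignments, `[[`, numeric(1), "fraction")))
  }))
  max(sums)
}
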