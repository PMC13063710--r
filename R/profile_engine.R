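#' Availability profiles and their decimal codes
#'
#' A profile is a binary vector over the omics blocks in fixed order, with 1
#' marking an observed block. Profiles are encoded as decimal integers with
#' the leftmost block (position 0) as the most significant bit, so with four
#' blocks `[rs, cn, mu, pp]` the profile `[1,0,1,1]` has code 11 and
#' `[1,0,1,0]` has code 10.
#'
#' @param bits integer vector of 0/1, length = number of blocks
#' @return `to_decimal`: the integer code. `from_decimal`: the bit vector.
#' @examples
#' to_decimal(c(1, 0, 1, 1)) # 11
#' from_decimal(10, 4)       # 1 0 1 0
#' @export
to_decimal <- function(bits) {
  bits <- as.integer(bits)
  if (length(bits) < 1L) stop("profile must have length >= 1")
  if (!all(bits %in% c(0L, 1L))) stop("profile bits must be 0/1")
  as.integer(sum(bits * 2^((length(bits) - 1L):0L)))
}

#' @rdname to_decimal
#' @param code integer in `[0, 2^S - 1]`
#' @param S number of blocks
#' @export
from_decimal <- function(code, S) {
  if (S < 1L) stop("S must be >= 1")
  if (code < 0 || code > 2^S - 1) {
    stop("code ", code, " outside [0, ", 2^S - 1, "]")
  }
  as.integer(bitwAnd(bitwShiftR(as.integer(code), (S - 1L):0L), 1L))
}

#' Profile of a sample from its per-feature observation mask
#'
#' @param sample_mask logical vector over features, `TRUE` = observed
#' @param blocks named list of feature-id vectors (or a
#'   `multiomics_dataset`'s block list); `sample_mask` must be named by
#'   feature id, or ordered to match the concatenated block features.
#' @return object of class `omics_profile`: list with `bits` and `code`
#' @details Each block must be fully observed or fully missing (the
#'   block-wise missingness contract); partially observed blocks and
#'   all-missing samples are errors, not coerced.
#' @export
profile_of <- function(sample_mask, blocks) {
  if (inherits(blocks, "multiomics_dataset")) blocks <- block_feature_list(blocks)
  feats <- unlist(blocks, use.names = FALSE)
  if (!is.null(names(sample_mask))) {
    sample_mask <- sample_mask[feats]
  } else if (length(sample_mask) != length(feats)) {
    stop("sample_mask length does not match block features")
  }
  bits <- integer(length(blocks))
  offset <- 0L
  for (i in seq_along(blocks)) {
    m <- sample_mask[(offset + 1L):(offset + length(blocks[[i]]))]
    offset <- offset + length(blocks[[i]])
    if (all(m)) {
      bits[i] <- 1L
    } else if (any(m)) {
      stop("block '", names(blocks)[i] %||% i,
           "' is partially observed; block-wise missingness violated")
    }
  }
  if (all(bits == 0L)) stop("sample has no observed block")
  new_profile(bits)
}

new_profile <- function(bits) {
  structure(list(bits = as.integer(bits), code = to_decimal(bits)),
            class = "omics_profile")
}

#' @export
print.omics_profile <- function(x, ...) {
  cat(sprintf("profile %s (code %d)\n", paste(x$bits, collapse = ""), x$code))
  invisible(x)
}

#' Profile codes of every sample in a dataset
#' @param ds a `multiomics_dataset`
#' @return integer vector of decimal profile codes, one per sample
#' @export
profile_codes <- function(ds) {
  blocks <- block_feature_list(ds)
  vapply(seq_len(n_samples(ds)),
         function(i) profile_of(ds$mask[i, ], blocks)$code,
         integer(1))
}

#' Enumerate all non-zero profiles for S blocks
#' @param S number of blocks, `S >= 1`
#' @return list of `2^S - 1` `omics_profile` objects, code ascending
#' @export
enumerate_profiles <- function(S) {
  if (S < 1L) stop("S must be >= 1")
  lapply(seq_len(2^S - 1), function(code) new_profile(from_decimal(code, S)))
}

#' Build overlapping profile subsets by containment
#'
#' For each distinct profile code `q` among the sample profiles, the subset
#' keyed by `q` holds every sample whose own profile `p` contains `q`
#' (`q AND p == q`): a sample with profile `[1,0,1,1]` (11) also belongs to
#' the subset for `[1,0,1,0]` (10). Overlap between subsets is deliberate —
#' every sample is reused wherever its observed blocks suffice.
#'
#' @param codes integer vector of per-sample profile codes (all non-zero)
#' @param S number of blocks
#' @param keys optional integer vector of subset keys to materialize;
#'   defaults to the distinct observed codes (only trainable subsets).
#' @return named list (names = decimal codes, ascending) of integer sample
#'   index vectors in input order; empty subsets are omitted.
#' @export
build_subsets <- function(codes, S, keys = NULL) {
  codes <- as.integer(codes)
  if (any(codes <= 0L)) stop("all sample profiles must be non-zero")
  if (any(codes > 2^S - 1)) stop("profile code exceeds 2^S - 1")
  keys <- sort(unique(as.integer(keys %||% codes)))
  out <- list()
  for (q in keys) {
    members <- which(bitwAnd(codes, q) == q)
    if (length(members)) out[[as.character(q)]] <- members
  }
  out
}

#' Superset compatibility between profiles
#'
#' A candidate model profile is compatible with a test sample's profile when
#' it has a 1 wherever the test profile has a 1, i.e. the model consumes all
#' of the sample's observed blocks (and possibly more, to be imputed).
#'
#' @param test,candidate `omics_profile` objects or 0/1 bit vectors of equal
#'   length
#' @return logical
#' @export
is_superset_compatible <- function(test, candidate) {
  tb <- profile_bits(test); cb <- profile_bits(candidate)
  if (length(tb) != length(cb)) stop("profile length mismatch")
  all(cb[tb == 1L] == 1L)
}

profile_bits <- function(p) {
  if (inherits(p, "omics_profile")) p$bits else as.integer(p)
}

#' Hamming distance between two profiles
#' @param p,q `omics_profile` objects or 0/1 bit vectors of equal length
#' @return integer count of differing positions
#' @export
hamming <- function(p, q) {
  pb <- profile_bits(p); qb <- profile_bits(q)
  if (length(pb) != length(qb)) stop("profile length mismatch")
  sum(pb != qb)
}
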