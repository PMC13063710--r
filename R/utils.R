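#' @importFrom stats predict pnorm qnorm psignrank runif rnorm rbinom sd setNames
#' @importFrom utils read.delim write.table head
NULL

# Round half away from zero (base round() rounds half to even).
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Derive a reproducible child seed (< 2^31) from a master seed and a label,
# so split / injection / oversampling / model fits consume independent streams.
derive_seed <- function(seed, salt) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- 0
  for (ch in utf8ToInt(as.character(salt))) {
    h <- (h * 31 + ch) %% 2147483629
  }
  as.integer((abs(seed) * 48271 + h) %% 2147483629 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
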