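#' Specification for the synthetic multi-omics generator
#'
#' The generator emulates the structural features the strategies depend on:
#' several feature blocks sharing latent factors (cross-block redundant
#' signal, so any single block can partially stand in for another), a
#' binary outcome coupled to the latent factors, strong class imbalance,
#' and complete observation prior to missingness injection. It does not
#' attempt to match any real cohort's marginal distributions or biology.
#'
#' @param n_samples number of samples
#' @param block_sizes named integer vector / list of feature counts per
#'   block, in the fixed block order
#' @param n_latent shared latent dimension (default 3)
#' @param effect outcome-latent coupling strength; 0 = labels carry no
#'   signal (default 2)
#' @param noise_sd block-agnostic feature noise SD on top of the latent
#'   contribution (default 1)
#' @param minority_fraction target positive-class rate in (0, 0.5]
#'   (default 0.13, a strongly imbalanced survival-style outcome)
#' @param binarize_blocks names of blocks rendered 0/1 by thresholding at
#'   zero (mutation-like layers)
#' @param seed integer seed
#' @return object of class `generator_spec`
#' @export
generator_spec <- function(n_samples,
                           block_sizes = c(rs = 25, cn = 25, mu = 25, pp = 25),
                           n_latent = 3L, effect = 2, noise_sd = 1,
                           minority_fraction = 0.13,
                           binarize_blocks = character(0), seed = 1L) {
  block_sizes <- unlist(block_sizes)
  if (is.null(names(block_sizes)) || any(names(block_sizes) == "")) {
    stop("block_sizes must be named")
  }
  if (n_latent < 1L) stop("n_latent must be >= 1")
  if (!(minority_fraction > 0 && minority_fraction <= 0.5)) {
    stop("minority_fraction must be in (0, 0.5]")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(
    list(n_samples = as.integer(n_samples), block_sizes = block_sizes,
         n_latent = as.integer(n_latent), effect = effect,
         noise_sd = noise_sd, minority_fraction = minority_fraction,
         binarize_blocks = binarize_blocks, seed = as.integer(seed)),
    class = "generator_spec")
}

# shared core: latent factors, per-block loadings, noise, latent score
synthesize_values <- function(spec) {
  n <- spec$n_samples
  L <- spec$n_latent
  Z <- matrix(rnorm(n * L), n, L)
  blocks <- list()
  values <- NULL
  for (b in names(spec$block_sizes)) {
    p <- spec$block_sizes[[b]]
    # loadings scaled 1/sqrt(L) keep feature variances comparable
    W <- matrix(rnorm(L * p, sd = 1 / sqrt(L)), L, p)
    X <- Z %*% W + spec$noise_sd * matrix(rnorm(n * p), n, p)
    if (b %in% spec$binarize_blocks) {
      X <- (X > 0) + 0
    }
    colnames(X) <- paste0(b, "_", seq_len(p))
    blocks[[b]] <- colnames(X)
    values <- cbind(values, X)
  }
  score <- as.numeric(Z %*% rep(1 / sqrt(L), L))
  list(values = values, blocks = blocks, score = score)
}

# intercept such that mean sigmoid(effect * score + c) = target rate
solve_intercept <- function(eta, target) {
  stats::uniroot(function(c) mean(1 / (1 + exp(-(eta + c)))) - target,
                 interval = c(-50, 50))$root
}

#' Generate a complete synthetic multi-omics dataset
#'
#' Latent factors are standard normal per sample; each block is a random
#' linear read-out of the factors plus independent noise (thresholded to
#' 0/1 for blocks listed in `binarize_blocks`); labels are Bernoulli with
#' `sigmoid(effect * latent_score + intercept)`, the intercept solved
#' numerically so the expected positive rate equals `minority_fraction`.
#' Fully observed; deterministic per seed.
#'
#' @param spec a [generator_spec()]
#' @return a complete labelled [multiomics_dataset()]
#' @export
generate_complete <- function(spec) {
  if (!inherits(spec, "generator_spec")) stop("need a generator_spec")
  withr::with_seed(spec$seed, {
    syn <- synthesize_values(spec)
    eta <- spec$effect * syn$score
    intercept <- solve_intercept(eta, spec$minority_fraction)
    labels <- rbinom(spec$n_samples, 1L, 1 / (1 + exp(-(eta + intercept))))
    multiomics_dataset(syn$values, blocks = syn$blocks, labels = labels)
  })
}

#' A BRCA-shaped synthetic fixture
#'
#' A synthetic stand-in with the shape of the public four-omics breast
#' cancer cohort this framework targets: 705 samples, blocks rs = 604,
#' cn = 860, mu = 249 (binarized), pp = 223 features (1936 in total) in the
#' fixed order `[rs, cn, mu, pp]`, and exactly 611 negative ("alive") / 94
#' positive
#' ("deceased") labels, assigned by ranking the latent outcome score and
#' cutting at the 94 highest. Complete mask. The content is synthetic —
#' only shape, block structure, imbalance and cross-block redundancy are
#' emulated.
#'
#' @param seed integer seed
#' @return a complete labelled [multiomics_dataset()], 705 x 1936
#' @export
brca_like_fixture <- function(seed = 1L) {
  spec <- generator_spec(
    n_samples = 705,
    block_sizes = c(rs = 604, cn = 860, mu = 249, pp = 223),
    n_latent = 3L, effect = 2, noise_sd = 1,
    minority_fraction = 94 / 705, binarize_blocks = "mu", seed = seed)
  withr::with_seed(spec$seed, {
    syn <- synthesize_values(spec)
    labels <- integer(spec$n_samples)
    labels[order(syn$score, decreasing = TRUE)[1:94]] <- 1L
    multiomics_dataset(syn$values, blocks = syn$blocks, labels = labels)
  })
}
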