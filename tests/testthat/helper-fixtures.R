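# Small builders shared across the suite. Everything is generated in code;
# no fixture files.

# deterministic little four-block dataset with labels
toy_dataset <- function(n = 60, per_block = 3, seed = 1, effect = 2,
                        minority_fraction = 0.25) {
  generate_complete(generator_spec(
    n_samples = n,
    block_sizes = c(rs = per_block, cn = per_block,
                    mu = per_block, pp = per_block),
    n_latent = 2L, effect = effect, noise_sd = 0.5,
    minority_fraction = minority_fraction, seed = seed))
}

# hand-built 2-block dataset where every value is known exactly
tiny_manual_dataset <- function() {
  vals <- matrix(c(0, 5, 10,
                   1, 2, 3,
                   10, 20, 30,
                   -1, 0, 1,
                   100, 200, 300),
                 nrow = 3, ncol = 5,
                 dimnames = list(NULL, c("a1", "a2", "b1", "b2", "b3")))
  multiomics_dataset(vals,
                     blocks = list(A = c("a1", "a2"),
                                   B = c("b1", "b2", "b3")),
                     labels = c(0L, 0L, 1L))
}

# independent O(n^2 d) reference for the distance-weighted KNN fill
knn_oracle <- function(x, donors, k) {
  x <- rbind(x); donors <- as.matrix(donors)
  d_total <- ncol(donors)
  out <- x
  for (i in seq_len(nrow(x))) {
    for (j in which(is.na(x[i, ]))) {
      dist <- vapply(seq_len(nrow(donors)), function(r) {
        shared <- which(!is.na(x[i, ]) & !is.na(donors[r, ]))
        if (!length(shared)) return(Inf)
        sqrt(d_total / length(shared) *
               sum((x[i, shared] - donors[r, shared])^2))
      }, numeric(1))
      cand <- which(!is.na(donors[, j]) & is.finite(dist))
      cand <- cand[order(dist[cand], cand)]
      cand <- cand[seq_len(min(k, length(cand)))]
      dd <- dist[cand]
      out[i, j] <- if (any(dd == 0)) {
        mean(donors[cand[dd == 0], j])
      } else {
        sum(donors[cand, j] / dd) / sum(1 / dd)
      }
    }
  }
  out
}

# full sign-flip enumeration oracle for the exact Wilcoxon two-sided p
wilcoxon_enumeration_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ws <- vapply(seq_len(2^n) - 1L, function(m) {
    signs <- bitwAnd(bitwShiftR(m, seq_len(n) - 1L), 1L)
    sum(r[signs == 1L])
  }, numeric(1))
  mean(abs(ws - mu) >= abs(W_obs - mu) - 1e-9)
}
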