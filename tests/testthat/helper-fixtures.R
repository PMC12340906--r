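## Shared fixture builders. Everything is generated in code; seeds are fixed
## so expected values frozen in the tests are reproducible.

## Two (or three) well-separated Gaussian clouds as a probes x samples matrix.
make_clouds <- function(n_per = 20, p = 50, k = 2, sep = 8, sd = 0.5,
                        seed = 42) {
  set.seed(seed)
  centers <- matrix(rnorm(k * p), k, p) * 0
  for (g in seq_len(k)) centers[g, seq_len(5) + (g - 1) * 5] <- sep
  x <- do.call(rbind, lapply(seq_len(k), function(g) {
    matrix(rnorm(n_per * p, 0, sd), n_per, p) +
      matrix(centers[g, ], n_per, p, byrow = TRUE)
  }))
  rownames(x) <- sprintf("s%02d", seq_len(nrow(x)))
  colnames(x) <- sprintf("f%03d", seq_len(p))
  list(x = t(x), labels = rep(seq_len(k), each = n_per))
}

## Tiny sample table for residualization tests.
make_samples <- function(n, seed = 7) {
  set.seed(seed)
  data.frame(sample_id = sprintf("s%02d", seq_len(n)),
             diagnosis = rep(c("LOAD", "HC"), length.out = n),
             age = rnorm(n, 70, 5),
             sex = rbinom(n, 1, 0.5),
             batch = sample(c("b1", "b2"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

## Small simulation config used across tests.
small_config <- function(seed = 1, ...) {
  sim_config(n_samples_per_cohort = 60, n_controls = 20, n_probes = 1200,
             n_genes = 600, n_causal_genes = 30, seed = seed, ...)
}
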