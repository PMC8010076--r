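# Independent oracles and small fixtures shared across test files.

# Brute-force Benjamini-Hochberg step-up: q(i) = min_{j >= i} p_(j) * m / j
# on the ascending sort, clipped to 1, returned in input order. Written
# directly from the definition, independent of any adjustment routine.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    js <- i:m
    q_sorted[i] <- min(1, min(m / js * p[ord][js]))
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# Exhaustive hypergeometric upper tail: probability that a uniformly random
# size-n draw from the universe overlaps the set in at least k elements,
# enumerated over all draws.
hyper_oracle <- function(universe_size, set_size, draw_size, k) {
  draws <- utils::combn(universe_size, draw_size)
  # the "set" is elements 1..set_size without loss of generality
  overlaps <- apply(draws, 2, function(d) sum(d <= set_size))
  mean(overlaps >= k)
}

# Small noise-free configuration used by exactness tests.
noisefree_config <- function(n = 400, frac = 0.05, seed = 5,
                             sign_mode = "median_neutral") {
  sim_config(n_proteins = n, frac_regulated = frac, noise_sd_within = 0,
             noise_sd_tech = 0, run_offset_sd = 0, missing_rate = 0,
             sign_mode = sign_mode, seed = seed)
}

truth_effect_at <- function(truth, protein_id, condition) {
  truth$effects[cbind(match(protein_id, rownames(truth$effects)),
                      match(condition, colnames(truth$effects)))]
}
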