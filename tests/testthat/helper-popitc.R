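# deterministic toy IPD used across tests
toy_ipd <- function(n = 60, k = 2, seed = 42, em_idx = seq_len(k)) {
  set.seed(seed)
  x <- matrix(rnorm(n * k, 0.3, 0.4), n, k)
  z <- rep(c(1L, 0L), length.out = n)
  y <- rbinom(n, 1L, plogis(-0.3 + rowSums(x) + (-1 + 0.5 * x[, 1]) * z))
  trial_ipd(x, z, y, em_idx = em_idx)
}

# benchmark configuration shared by simulation-based tests
bench_cfg <- function(...) scenario_config(...)

expit <- function(x) 1 / (1 + exp(-x))
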