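# Shared fixtures, built once per test run and memoized.

fixture_env <- new.env(parent = emptyenv())

# small two-day benchmark: 6 trials/day, one extra cycle per trial
small_benchmark <- function() {
  if (is.null(fixture_env$bench)) {
    fixture_env$bench <- generate_benchmark(
      protocol_spec(n_trials = 6, extra_cycles = 1),
      days = c(1, 2), seed = 202L)
  }
  fixture_env$bench
}

# single short trial (fast unit tests)
small_trial <- function() small_benchmark()$days[["1"]][[1]]

# smooth envelope-like toy regression set: per-window channel levels with a
# mild within-window ripple, target a fixed linear map of the levels
toy_windows <- function(nw, len = 32L, seed = 7L) {
  set.seed(seed)
  lev <- matrix(runif(nw * 4), nw, 4)
  X <- array(0, c(nw, len, 4))
  ripple <- outer(sin(2 * pi * seq_len(len) / len), rep(0.1, 4))
  for (w in seq_len(nw))
    X[w, , ] <- matrix(lev[w, ], len, 4, byrow = TRUE) * (1 + ripple)
  y <- as.numeric(lev %*% c(2, -1, 0.5, 1))
  windowed_dataset(X, y, len, 16L)
}

tiny_arch <- function(batch_norm = TRUE, dropout = 0.01)
  cnn_architecture(1, 16, 3, 16, batch_norm, dropout)
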