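# Small simulation configurations used across the test files. Tests run on
# reduced problem sizes (few channels, 128 Hz) so the suite stays fast; the
# full study conditions are exercised by scripts/acceptance.R.

small_config <- function(mode = "negative", snr = 4, n_trials = 64,
                         n_channels = 16, sample_rate = 128, seed = 1L,
                         ...) {
  simulation_config(n_trials = n_trials, n_channels = n_channels,
                    correlation_mode = mode, snr = snr,
                    sample_rate = sample_rate, seed = seed, ...)
}

# noise-free dataset: signal only, for exact arithmetic checks
noiseless_config <- function(mode = "negative", seed = 1L, ...) {
  small_config(mode = mode, seed = seed, noise_amplitude = 0, ...)
}

# epochs with a single constant-value trial, for baseline tests
constant_epochs <- function(value = 5, n_channels = 2, sample_rate = 128) {
  times <- seq(-300, 800, by = 1000 / sample_rate)
  data <- array(value, dim = c(1, n_channels, length(times)))
  epochs_set(data, sample_rate, times, paste0("CH", seq_len(n_channels)),
             data.frame(condition = "test"))
}

# exhaustive O(n^2) pairwise AUC oracle (ties count one half)
auc_oracle <- function(scores, labels, positive) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  total <- 0
  for (a in pos) for (b in neg)
    total <- total + (a > b) + 0.5 * (a == b)
  total / (length(pos) * length(neg))
}
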