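# Shared fixtures. Everything is generated in code; heavyweight objects are
# cached per session so several test files (and several criteria within the
# acceptance file) can share them.

.fixture_cache <- new.env(parent = emptyenv())

cache_fixture <- function(key, build) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- build()
  .fixture_cache[[key]]
}

# Small, fast config used by module tests: 4 participants, 16 channels,
# 128 Hz, accuracies capped so 8-fold stratification is always feasible.
small_config <- function(...) {
  base <- list(n_participants = 4, n_blocks = 4, trials_per_block = 42,
               accuracy_range = c(0.65, 0.85), fs_raw = 128, n_channels = 16,
               seed = 11)
  do.call(sim_config, utils::modifyList(base, list(...)))
}

small_run <- function() {
  cache_fixture("small_run", function() run_pipeline(small_config()))
}

# The default synthetic benchmark of the acceptance criteria: 10
# participants, accuracies 0.65-0.95, 12 blocks x 42 trials with one third
# empty (336 decision trials), seed 42. The raw EEG rate is scaled down from
# 2048 Hz to 256 Hz purely for run-time budget; the conditioned output
# (32 Hz, 48 samples) is identical in shape and the test assertions do not
# depend on the raw rate.
benchmark_config <- function() sim_config(fs_raw = 256, seed = 42)

benchmark_run <- function() {
  cache_fixture("benchmark_run", function() run_pipeline(benchmark_config()))
}

benchmark_tables <- function() {
  cache_fixture("benchmark_tables", function()
    run_strategies(benchmark_run(), group_sizes = 1:10, n_boot = 200L))
}

# Bind trials x channels x samples arrays along the trial axis.
abind3 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  out <- array(0, dim = c(sum(vapply(parts, function(p) dim(p)[1], 0L)),
                          d[2], d[3]))
  at <- 1L
  for (p in parts) {
    out[at:(at + dim(p)[1] - 1L), , ] <- p
    at <- at + dim(p)[1]
  }
  out
}

# Seeded evaluation without disturbing the suite's RNG stream.
with_seed_for_tests <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Deterministic multichannel sinusoid testbed for filter specs.
sinusoid_eeg <- function(freqs, fs = 2048, dur = 8, channels = NULL) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  x <- do.call(rbind, lapply(freqs, function(f)
    if (f == 0) rep(1, length(t)) else sin(2 * pi * f * t)))
  channels <- channels %||% sprintf("S%02d", seq_along(freqs))
  continuous_eeg(x, fs = fs, channel_names = channels)
}

# Amplitude of a sinusoid estimated away from filter edge transients.
mid_amplitude <- function(x, fs, skip_s = 2) {
  i <- round(skip_s * fs):(length(x) - round(skip_s * fs))
  (max(x[i]) - min(x[i])) / 2
}
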