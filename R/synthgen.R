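# Synthetic multi-participant experiment generator.
#
# The simulator stands in for unavailable recordings: it produces behaviour
# (decisions, response times, reported confidences), response-locked EEG
# epochs with a fronto-central correct-vs-incorrect amplitude difference, and
# per-trial frame streams with a hidden stimulus-onset step. Every statistical
# feature the downstream pipeline relies on is generated explicitly and is
# therefore recoverable in tests.

# 64-channel 10-20-style montage (Biosemi layout ordering). Includes the
# channels the pipeline requires by name: Fp1, F1, Fp2, F2, FCz.
biosemi64_channels <- function(n = 64) {
  labs <- c(
    "Fp1", "AF7", "AF3", "F1", "F3", "F5", "F7", "FT7", "FC5", "FC3", "FC1",
    "C1", "C3", "C5", "T7", "TP7", "CP5", "CP3", "CP1", "P1", "P3", "P5",
    "P7", "P9", "PO7", "PO3", "O1", "Iz", "Oz", "POz", "Pz", "CPz", "Fpz",
    "Fp2", "AF8", "AF4", "AFz", "Fz", "F2", "F4", "F6", "F8", "FT8", "FC6",
    "FC4", "FC2", "FCz", "Cz", "C2", "C4", "C6", "T8", "TP8", "CP6", "CP4",
    "CP2", "P2", "P4", "P6", "P8", "P10", "PO8", "PO4", "O2")
  if (n == 64) return(labs)
  required <- c("Fp1", "F1", "Fp2", "F2", "FCz", "Fz", "Cz", "FC1", "FC2")
  if (n < length(required))
    stop_param("n_channels must be at least %d", length(required))
  c(required, setdiff(labs, required))[seq_len(n)]
}

# Fronto-central spatial profile of the response-locked component.
fronto_central_weights <- function(channel_names) {
  w <- rep(0.15, length(channel_names))
  names(w) <- channel_names
  hot <- c(FCz = 1, FC1 = 0.9, FC2 = 0.9, Fz = 0.8, Cz = 0.8,
           F1 = 0.6, F2 = 0.6, C1 = 0.6, C2 = 0.6, AFz = 0.4, CPz = 0.4)
  hit <- intersect(names(hot), channel_names)
  w[hit] <- hot[hit]
  w
}

#' Simulation configuration
#'
#' Declares the full stated world of a synthetic experiment. Defaults follow
#' the patrol-style design: 10 participants, 12 blocks of 42 trials with one
#' third empty doors (336 decision trials), 2.5 s response deadline, 2 s
#' confidence-reporting window on the 11-point 0--100 scale, 4 Hz frames,
#' 64-channel EEG at 2048 Hz.
#'
#' @param n_participants number of participants.
#' @param n_blocks,trials_per_block block structure of the session.
#' @param fraction_empty proportion of trials with no character (no decision
#'   required), in `[0, 1)`.
#' @param accuracy_range per-participant true accuracy is drawn uniformly
#'   within this interval; must lie in `(0.5, 1]`.
#' @param erp_effect amplitude difference (uV) of the response-locked
#'   component between incorrect and correct trials.
#' @param erp_base baseline component amplitude (uV) common to both classes.
#' @param erp_window_ms component support relative to the response (ms).
#' @param noise_sd standard deviation (uV) of the 1/f background noise.
#' @param fs_raw raw EEG sampling rate (Hz); must be a multiple of 32.
#' @param n_channels electrode count (10-20 labels, includes FCz/Fp1/F1/...).
#' @param rt_meanlog_range range of per-participant lognormal RT locations.
#' @param rt_sdlog lognormal scale of RTs.
#' @param rt_shift_incorrect additive meanlog shift for incorrect trials
#'   (errors are slower).
#' @param acc_rt_correlation Gaussian-copula correlation between participant
#'   accuracy and RT location; negative means better participants are faster.
#' @param conf_effect separation (logit units) of the latent confidence
#'   evidence between correct and incorrect trials.
#' @param conf_noise_sd reported-confidence noise, in confidence points.
#' @param response_deadline_s decision deadline (s).
#' @param conf_deadline_s confidence-reporting window after the response (s).
#' @param disappearance_range_s optional `c(min, max)`: the character
#'   disappears after a uniform random time; slower responses are recorded as
#'   missing and labelled incorrect (outpost-style rule). `NULL` disables.
#' @param frame_rate_hz frame rate of the simulated video stream (4 or 10).
#' @param frame_step mean-RGB step magnitude at the hidden onset.
#' @param frame_jitter_sd background mean-RGB jitter between frames.
#' @param frame_miss_fraction fraction of non-empty trials whose onset step is
#'   made sub-threshold (exercises the previous-onset fallback).
#' @param trial_period_s spacing between consecutive trial onset windows (s).
#' @param seed integer seed; identical configs regenerate identical datasets.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_participants = 10, n_blocks = 12,
                       trials_per_block = 42, fraction_empty = 1 / 3,
                       accuracy_range = c(0.65, 0.95), erp_effect = 6,
                       erp_base = 2, erp_window_ms = c(-500, 0),
                       noise_sd = 12, fs_raw = 2048, n_channels = 64,
                       rt_meanlog_range = c(-0.7, 0.1), rt_sdlog = 0.35,
                       rt_shift_incorrect = 0.25, acc_rt_correlation = -0.8,
                       conf_effect = 1.0, conf_noise_sd = 15,
                       response_deadline_s = 2.5, conf_deadline_s = 2.0,
                       disappearance_range_s = NULL, frame_rate_hz = 4,
                       frame_step = 20, frame_jitter_sd = 0.5,
                       frame_miss_fraction = 0, trial_period_s = 6,
                       seed = 1L) {
  cfg <- list(
    n_participants = as.integer(n_participants), n_blocks = as.integer(n_blocks),
    trials_per_block = as.integer(trials_per_block),
    fraction_empty = fraction_empty, accuracy_range = accuracy_range,
    erp_effect = erp_effect, erp_base = erp_base,
    erp_window_ms = erp_window_ms, noise_sd = noise_sd,
    fs_raw = as.integer(fs_raw), n_channels = as.integer(n_channels),
    rt_meanlog_range = rt_meanlog_range, rt_sdlog = rt_sdlog,
    rt_shift_incorrect = rt_shift_incorrect,
    acc_rt_correlation = acc_rt_correlation, conf_effect = conf_effect,
    conf_noise_sd = conf_noise_sd, response_deadline_s = response_deadline_s,
    conf_deadline_s = conf_deadline_s,
    disappearance_range_s = disappearance_range_s,
    frame_rate_hz = frame_rate_hz, frame_step = frame_step,
    frame_jitter_sd = frame_jitter_sd,
    frame_miss_fraction = frame_miss_fraction,
    trial_period_s = trial_period_s, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_participants < 1 || n_blocks < 1 || trials_per_block < 1)
      stop_param("counts must be positive")
    if (fraction_empty < 0 || fraction_empty >= 1)
      stop_param("fraction_empty must be in [0, 1)")
    if (accuracy_range[1] <= 0.5 || accuracy_range[2] > 1 ||
        accuracy_range[1] > accuracy_range[2])
      stop_param("accuracy_range must lie within (0.5, 1]")
    if (abs(acc_rt_correlation) > 1)
      stop_param("acc_rt_correlation must be in [-1, 1]")
    if (!frame_rate_hz > 0) stop_param("frame_rate_hz must be positive")
    if (noise_sd < 0 || conf_noise_sd < 0) stop_param("noise SDs must be >= 0")
    # the RT support must fit inside the deadline, otherwise truncation is
    # degenerate: require the 1st percentile of the slowest participant's
    # correct-trial RT to be below the deadline
    slowest_q01 <- exp(max(rt_meanlog_range) + rt_shift_incorrect -
                         2.33 * rt_sdlog)
    if (slowest_q01 >= response_deadline_s)
      stop_param("response deadline (%gs) is below the RT support", response_deadline_s)
    if (!is.null(disappearance_range_s) &&
        (length(disappearance_range_s) != 2 ||
         disappearance_range_s[1] > disappearance_range_s[2] ||
         disappearance_range_s[1] <= 0))
      stop_param("disappearance_range_s must be an increasing positive pair")
  })
  invisible(cfg)
}

# Draw participant skill: accuracy and RT location coupled via a Gaussian
# copula so that better performers are also faster when the correlation is
# negative.
draw_participants <- function(cfg) {
  n <- cfg$n_participants
  rho <- cfg$acc_rt_correlation
  z1 <- rnorm(n)
  z2 <- rho * z1 + sqrt(max(0, 1 - rho^2)) * rnorm(n)
  acc <- cfg$accuracy_range[1] +
    (cfg$accuracy_range[2] - cfg$accuracy_range[1]) * pnorm(z1)
  meanlog <- cfg$rt_meanlog_range[1] +
    (cfg$rt_meanlog_range[2] - cfg$rt_meanlog_range[1]) * pnorm(z2)
  data.frame(participant_id = sprintf("P%02d", seq_len(n)),
             true_accuracy = acc, rt_meanlog = meanlog,
             stringsAsFactors = FALSE)
}

# Shared trial sequence: labels, block indices, hidden onset times.
draw_trial_info <- function(cfg) {
  n_trials <- cfg$n_blocks * cfg$trials_per_block
  n_empty <- round(cfg$fraction_empty * cfg$trials_per_block)
  per_block <- c(rep(0L, n_empty),
                 rep(c(1L, -1L), length.out = cfg$trials_per_block - n_empty))
  labels <- unlist(lapply(seq_len(cfg$n_blocks), function(b) sample(per_block)))
  onset_jitter <- runif(n_trials, 1, 2)
  start <- (seq_len(n_trials) - 1) * cfg$trial_period_s
  onset <- ifelse(labels != 0L, start + onset_jitter, NA_real_)
  disappearance <- if (!is.null(cfg$disappearance_range_s)) {
    runif(n_trials, cfg$disappearance_range_s[1], cfg$disappearance_range_s[2])
  } else rep(NA_real_, n_trials)
  missed <- rep(FALSE, n_trials)
  nonempty <- which(labels != 0L)
  if (cfg$frame_miss_fraction > 0) {
    k <- round(cfg$frame_miss_fraction * length(nonempty))
    if (k > 0) missed[sample(nonempty, k)] <- TRUE
  }
  data.frame(trial_id = seq_len(n_trials),
             block = rep(seq_len(cfg$n_blocks), each = cfg$trials_per_block),
             true_label = labels, trial_start_s = start,
             onset_time_s = onset, disappearance_s = disappearance,
             frame_missed = missed)
}

#' Simulate behaviour (decisions, RTs, reported confidences)
#'
#' Draws per-participant accuracies and RT distributions, a shared randomized
#' trial sequence with hidden onset times, and per-trial decisions, lognormal
#' RTs truncated at the deadline, and reported confidences on the 0--100
#' step-10 grid. Under the outpost-style rule (`disappearance_range_s` set),
#' trials where the sampled RT exceeds the disappearance time carry no
#' decision and are labelled incorrect.
#'
#' @param config a [sim_config()].
#' @return list with `trials` (one row per participant x trial, see
#'   [write_trials()] for the column contract), `participants` and
#'   `trial_info` (hidden ground truth).
#' @export
simulate_behaviour <- function(config) {
  validate_sim_config(config)
  with_seed(config$seed, {
    parts <- draw_participants(config)
    info <- draw_trial_info(config)
    trials <- do.call(rbind, lapply(seq_len(nrow(parts)), function(p) {
      simulate_participant_behaviour(parts[p, ], info, config)
    }))
    rownames(trials) <- NULL
    list(trials = trials, participants = parts, trial_info = info)
  })
}

simulate_participant_behaviour <- function(part, info, cfg) {
  n <- nrow(info)
  acc <- part$true_accuracy
  decision <- rep(NA_integer_, n)
  rt <- rep(NA_real_, n)
  conf <- rep(NA_integer_, n)
  conf_ts <- rep(NA_real_, n)
  nonempty <- info$true_label != 0L
  correct <- rep(NA, n)
  correct[nonempty] <- runif(sum(nonempty)) < acc

  for (i in which(nonempty)) {
    ml <- part$rt_meanlog + if (correct[i]) 0 else cfg$rt_shift_incorrect
    r <- rlnorm(1, ml, cfg$rt_sdlog)
    tries <- 0
    while (r >= cfg$response_deadline_s && tries < 20) {
      r <- rlnorm(1, ml, cfg$rt_sdlog); tries <- tries + 1
    }
    if (r >= cfg$response_deadline_s) r <- cfg$response_deadline_s - 1e-3
    if (!is.na(info$disappearance_s[i]) && r > info$disappearance_s[i]) {
      correct[i] <- FALSE # no response in time: recorded as incorrect
      next
    }
    rt[i] <- r
    decision[i] <- if (correct[i]) info$true_label[i] else -info$true_label[i]
    evidence <- qlogis(acc) + cfg$conf_effect * (if (correct[i]) 1 else -1)
    raw <- 100 * plogis(evidence) + rnorm(1, 0, cfg$conf_noise_sd)
    conf[i] <- as.integer(10 * round(pmin(100, pmax(0, raw)) / 10))
    conf_ts[i] <- info$onset_time_s[i] + r +
      runif(1, 0.3, cfg$conf_deadline_s)
  }
  correctness <- rep(NA_character_, n)
  correctness[nonempty] <- ifelse(correct[nonempty], "correct", "incorrect")
  data.frame(participant_id = part$participant_id, block = info$block,
             trial_id = info$trial_id, true_label = info$true_label,
             decision = decision,
             response_timestamp_s = info$onset_time_s + rt,
             reported_confidence = conf, confidence_timestamp_s = conf_ts,
             correctness = correctness, rt_true_s = rt,
             stringsAsFactors = FALSE)
}

# 1/f-shaped noise: white Gaussian spectrum shaped by 1/sqrt(f), scaled to a
# target time-domain SD. Returns an n_samples x n_series matrix (vectorized
# over series via mvfft).
pink_noise <- function(n_samples, n_series, sd_target) {
  n_out <- n_samples
  n_samples <- stats::nextn(n_samples, 2) # fast FFT length; truncate after
  nf <- (n_samples - 1) %/% 2
  shape <- 1 / sqrt(seq_len(nf))
  amp <- shape * matrix(abs(rnorm(nf * n_series)), nf, n_series)
  phs <- matrix(runif(nf * n_series, 0, 2 * pi), nf, n_series)
  spec <- amp * exp(1i * phs)
  full <- matrix(0 + 0i, n_samples, n_series)
  full[2:(nf + 1), ] <- spec
  full[n_samples:(n_samples - nf + 1), ] <- Conj(spec)
  if (n_samples %% 2 == 0) # real Nyquist bin
    full[nf + 2, ] <- rnorm(n_series) / sqrt(nf + 1)
  x <- Re(stats::mvfft(full, inverse = TRUE))[seq_len(n_out), , drop = FALSE] /
    n_samples
  sds <- sqrt(pmax(colMeans(x^2) - colMeans(x)^2, .Machine$double.eps))
  x * rep(sd_target / sds, each = n_out)
}

#' Simulate response-locked EEG epochs
#'
#' Epochs cover `[-1700, +200]` ms around each answered response at the raw
#' rate: 1/f background noise plus a half-cosine response-locked component
#' inside `erp_window_ms`, larger for incorrect than correct trials by
#' `erp_effect` uV and spatially weighted toward fronto-central channels.
#' Empty and no-response trials produce no epoch.
#'
#' @param behaviour output of [simulate_behaviour()].
#' @param config the same [sim_config()].
#' @param participants restrict generation to these participant ids (useful to
#'   bound memory: generate and preprocess one participant at a time).
#' @return named list of `epoch_set` objects, one per participant.
#' @export
simulate_epochs <- function(behaviour, config,
                            participants = behaviour$participants$participant_id) {
  validate_sim_config(config)
  fs <- config$fs_raw
  n_pre <- round(1.7 * fs); n_post <- round(0.2 * fs)
  n_samp <- n_pre + n_post + 1L
  resp_idx <- n_pre + 1L
  ch <- biosemi64_channels(config$n_channels)
  spat <- fronto_central_weights(ch)
  tgrid <- (seq_len(n_samp) - resp_idx) / fs * 1000 # ms relative to response
  w0 <- config$erp_window_ms[1]; w1 <- config$erp_window_ms[2]
  inwin <- tgrid >= w0 & tgrid <= w1
  bump <- numeric(n_samp)
  bump[inwin] <- sin(pi * (tgrid[inwin] - w0) / (w1 - w0)) # half-cosine arch

  out <- list()
  for (pid in participants) {
    pseed <- derive_seed(config$seed, paste0("epochs-", pid))
    rows <- behaviour$trials[behaviour$trials$participant_id == pid, ]
    answered <- which(!is.na(rows$decision))
    n_ans <- length(answered)
    n_ch <- length(ch)
    labels <- rows$correctness[answered]
    dat <- with_seed(pseed, {
      # bulk 1/f noise, chunked over trials to bound memory
      flat <- matrix(0, n_samp, n_ans * n_ch)
      chunk <- max(1L, 200000L %/% (n_samp))
      starts <- seq(1L, n_ans, by = chunk)
      for (s0 in starts) {
        idx <- s0:min(n_ans, s0 + chunk - 1L)
        cols <- ((min(idx) - 1L) * n_ch + 1L):(max(idx) * n_ch)
        flat[, cols] <- pink_noise(n_samp, length(idx) * n_ch, config$noise_sd)
      }
      amp <- config$erp_base +
        ifelse(labels == "incorrect", config$erp_effect, 0)
      erp_unit <- outer(bump, spat) # n_samp x n_ch, negative-going below
      for (k in seq_len(n_ans)) {
        cols <- ((k - 1L) * n_ch + 1L):(k * n_ch)
        flat[, cols] <- flat[, cols] - amp[k] * erp_unit
      }
      aperm(array(flat, dim = c(n_samp, n_ch, n_ans)), c(3, 2, 1))
    })
    out[[pid]] <- epoch_set(dat, fs = fs, window_ms = c(-1700, 200),
                            trial_ids = rows$trial_id[answered],
                            labels = labels, channel_names = ch,
                            participant = pid)
  }
  out
}

#' Simulate per-trial frame streams
#'
#' Per-frame mean-RGB triplets at `frame_rate_hz` covering each trial window:
#' background jitter plus a persistent step change at the hidden onset frame.
#' Trials flagged `frame_missed` get a sub-threshold step (half the jitter SD)
#' to exercise the previous-onset fallback of the detector. Empty trials have
#' no step.
#'
#' @param behaviour output of [simulate_behaviour()].
#' @param config the same [sim_config()].
#' @return named list (by trial id) of frame-stream data frames with columns
#'   `frame_index`, `timestamp_s`, `mean_r`, `mean_g`, `mean_b`.
#' @export
simulate_frames <- function(behaviour, config) {
  validate_sim_config(config)
  info <- behaviour$trial_info
  dt <- 1 / config$frame_rate_hz
  base <- c(60, 60, 60)
  with_seed(derive_seed(config$seed, "frames"), {
    streams <- lapply(seq_len(nrow(info)), function(i) {
      t0 <- info$trial_start_s[i]
      ts <- seq(t0, t0 + config$trial_period_s - dt / 2, by = dt)
      nfr <- length(ts)
      rgb <- matrix(rep(base, each = nfr), nfr, 3) +
        matrix(rnorm(nfr * 3, 0, config$frame_jitter_sd), nfr, 3)
      if (!is.na(info$onset_time_s[i])) {
        k <- which(ts >= info$onset_time_s[i])[1]
        step <- if (info$frame_missed[i]) config$frame_jitter_sd / 2 else config$frame_step
        if (!is.na(k)) rgb[k:nfr, ] <- rgb[k:nfr, ] + step
      }
      data.frame(frame_index = seq_len(nfr), timestamp_s = ts,
                 mean_r = rgb[, 1], mean_g = rgb[, 2], mean_b = rgb[, 3])
    })
    names(streams) <- info$trial_id
    streams
  })
}

#' Simulate a complete experiment
#'
#' Convenience wrapper running [simulate_behaviour()], [simulate_epochs()] and
#' [simulate_frames()] under the config seed.
#'
#' @param config a [sim_config()].
#' @param with_epochs,with_frames generate the corresponding components
#'   (epochs dominate memory; disable when only behaviour is needed).
#' @return list of class `sim_dataset` with elements `trials`,
#'   `participants`, `trial_info`, `epochs`, `frames`, `config`.
#' @export
simulate_experiment <- function(config, with_epochs = TRUE, with_frames = TRUE) {
  beh <- simulate_behaviour(config)
  ds <- list(trials = beh$trials, participants = beh$participants,
             trial_info = beh$trial_info,
             epochs = if (with_epochs) simulate_epochs(beh, config) else NULL,
             frames = if (with_frames) simulate_frames(beh, config) else NULL,
             config = config)
  structure(ds, class = "sim_dataset")
}
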