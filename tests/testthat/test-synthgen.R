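# Synthetic experiment generator: determinism, behavioural statistics,
# frame/epoch structure, and parameter validation.

test_that("identical configs regenerate identical datasets", {
  cfg <- sim_config(n_participants = 3, n_blocks = 2, trials_per_block = 12,
                    accuracy_range = c(0.65, 0.85), fs_raw = 64,
                    n_channels = 16, seed = 7)
  a <- simulate_experiment(cfg)
  b <- simulate_experiment(cfg)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  # and a different seed gives different draws
  c2 <- simulate_behaviour(sim_config(n_participants = 3, n_blocks = 2,
                                      trials_per_block = 12,
                                      accuracy_range = c(0.65, 0.85),
                                      seed = 8))
  expect_false(identical(a$trials$response_timestamp_s,
                         c2$trials$response_timestamp_s))
})

test_that("behavioural statistics match the configured world", {
  # degenerate accuracy: every decision equals the truth
  cfg1 <- sim_config(n_participants = 2, n_blocks = 1, trials_per_block = 30,
                     accuracy_range = c(1, 1), seed = 3)
  beh1 <- simulate_behaviour(cfg1)
  ans <- beh1$trials[!is.na(beh1$trials$decision), ]
  expect_true(all(ans$decision == ans$true_label))

  # binomial oracle at the stated n: empirical accuracy within 3 binomial SDs
  cfg <- sim_config(seed = 5, fs_raw = 64) # 10 participants, 336 decision trials
  beh <- simulate_behaviour(cfg)
  for (p in seq_len(nrow(beh$participants))) {
    pid <- beh$participants$participant_id[p]
    acc0 <- beh$participants$true_accuracy[p]
    rows <- beh$trials[beh$trials$participant_id == pid &
                         beh$trials$true_label != 0, ]
    n <- nrow(rows)
    expect_equal(n, 336)
    emp <- mean(rows$correctness == "correct")
    expect_lt(abs(emp - acc0), 3 * sqrt(acc0 * (1 - acc0) / n))
  }

  # onset + true RT = response timestamp, exactly, for every answered trial
  tr <- merge(beh$trials, beh$trial_info[, c("trial_id", "onset_time_s")])
  ok <- !is.na(tr$response_timestamp_s)
  expect_equal(tr$response_timestamp_s[ok],
               tr$onset_time_s[ok] + tr$rt_true_s[ok], tolerance = 1e-12)

  # confidence: on-grid, correlates with correctness, higher when correct
  ans <- beh$trials[!is.na(beh$trials$decision), ]
  expect_true(all(ans$reported_confidence %% 10 == 0))
  sep <- confidence_separation(ans$reported_confidence,
                               ans$correctness)
  expect_gt(sep$difference, 0)
  expect_gt(cor(ans$reported_confidence,
                as.integer(ans$correctness == "correct")), 0)

  # accuracy-speed coupling: faster participants are more accurate
  mean_rt <- tapply(ans$rt_true_s, ans$participant_id, mean)
  accs <- beh$participants$true_accuracy
  expect_lt(cor(accs, mean_rt[beh$participants$participant_id]), 0)

  # RTs truncated at the deadline; confidence after the response
  expect_true(all(ans$rt_true_s < cfg$response_deadline_s))
  expect_true(all(ans$confidence_timestamp_s > ans$response_timestamp_s))
})

test_that("empty trials and the disappearance rule behave as specified", {
  cfg <- sim_config(n_participants = 2, n_blocks = 2, trials_per_block = 42,
                    accuracy_range = c(0.65, 0.85), seed = 9,
                    disappearance_range_s = c(0.3, 1.5), frame_rate_hz = 10)
  beh <- simulate_behaviour(cfg)
  info <- beh$trial_info
  # every non-empty trial has exactly one hidden onset; empty trials none
  expect_true(all(is.na(info$onset_time_s[info$true_label == 0])))
  expect_true(all(!is.na(info$onset_time_s[info$true_label != 0])))
  # slow trials are recorded as missing decisions labelled incorrect
  tr <- merge(beh$trials, info[, c("trial_id", "disappearance_s")])
  timed_out <- tr$true_label != 0 & is.na(tr$decision)
  expect_gt(sum(timed_out), 0) # the 0.3-1.5 s window must bite
  expect_true(all(tr$correctness[timed_out] == "incorrect"))
  expect_true(all(is.na(tr$reported_confidence[timed_out])))
})

test_that("frame streams carry the hidden onset at the configured rate", {
  for (rate in c(4, 10)) {
    cfg <- sim_config(n_participants = 2, n_blocks = 1, trials_per_block = 12,
                      accuracy_range = c(0.65, 0.85), frame_rate_hz = rate,
                      frame_jitter_sd = 0, seed = 13)
    beh <- simulate_behaviour(cfg)
    frames <- simulate_frames(beh, cfg)
    expect_length(frames, nrow(beh$trial_info))
    spacing <- diff(frames[[1]]$timestamp_s)
    expect_equal(spacing, rep(1 / rate, length(spacing)), tolerance = 1e-9)
    # with zero jitter there is exactly one supra-threshold change per
    # non-empty trial, at the first frame at/after the hidden onset
    for (i in seq_len(nrow(beh$trial_info))) {
      fr <- frames[[as.character(i)]]
      chg <- abs(diff(rowMeans(as.matrix(fr[, c("mean_r", "mean_g", "mean_b")]))))
      onset <- beh$trial_info$onset_time_s[i]
      if (is.na(onset)) {
        expect_true(all(chg < 1e-9))
      } else {
        k <- which(chg > cfg$frame_step / 2)
        expect_length(k, 1)
        expect_equal(fr$timestamp_s[k + 1],
                     fr$timestamp_s[min(which(fr$timestamp_s >= onset))])
      }
    }
  }
})

test_that("epoch simulation injects the stated component", {
  cfg <- sim_config(n_participants = 1, n_blocks = 2, trials_per_block = 30,
                    accuracy_range = c(0.65, 0.75), fs_raw = 128,
                    n_channels = 16, noise_sd = 0.01, erp_base = 0,
                    erp_effect = 5, seed = 21)
  beh <- simulate_behaviour(cfg)
  eps <- simulate_epochs(beh, cfg)[[1]]
  d <- dim(eps$data)
  expect_equal(d[2], cfg$n_channels)
  expect_equal(eps$fs, cfg$fs_raw)
  expect_equal(d[3], round(1.7 * 128) + round(0.2 * 128) + 1)
  # with near-zero noise, the incorrect-trial FCz amplitude inside the
  # window is ~erp_effect and the correct-trial amplitude ~0
  fcz <- match("FCz", eps$channel_names)
  resp <- round(1.7 * 128) + 1
  win <- (resp - round(0.25 * 128)):resp # centre of the (-500, 0) window
  amp <- apply(abs(eps$data[, fcz, win, drop = FALSE]), 1, max)
  expect_true(all(amp[eps$labels == "incorrect"] > 4))
  expect_true(all(amp[eps$labels == "correct"] < 1))
  # no epochs for unanswered trials
  expect_equal(d[1], sum(!is.na(beh$trials$decision)))
})

test_that("impossible parameter combinations are rejected", {
  expect_error(sim_config(accuracy_range = c(0.4, 0.9)), "accuracy_range")
  expect_error(sim_config(fraction_empty = 1), "fraction_empty")
  expect_error(sim_config(response_deadline_s = 0.05), "deadline")
  expect_error(sim_config(n_blocks = 0), "counts")
  expect_error(sim_config(disappearance_range_s = c(2, 1)), "disappearance")
})
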