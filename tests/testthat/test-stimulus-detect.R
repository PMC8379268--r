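# Onset reconstruction: backward scan, fallback rule, RT arithmetic, and
# exactness on synthetic streams.

mk_frames <- function(ts, vals) {
  data.frame(frame_index = seq_along(ts), timestamp_s = ts,
             mean_r = vals, mean_g = vals, mean_b = vals)
}

test_that("backward scan finds the most recent supra-threshold change", {
  ts <- seq(0, 5, by = 0.25)
  vals <- rep(60, length(ts))
  vals[ts >= 2] <- 80 # clean step at t = 2
  fr <- mk_frames(ts, vals)
  est <- detect_onset(fr, response_time = 3.1, threshold = 5)
  expect_equal(est$source, "detected")
  expect_equal(est$onset_time, 2)
  expect_equal(est$change_magnitude, 20)
  expect_equal(reconstruct_rt(est, 3.1), 1.1)

  # two steps before the response: the later one wins (brute-force check)
  vals2 <- vals; vals2[ts >= 2.75] <- 100
  fr2 <- mk_frames(ts, vals2)
  est2 <- detect_onset(fr2, response_time = 4, threshold = 5)
  chg <- c(NA, abs(diff(vals2)))
  brute <- max(which(chg > 5 & ts <= 4))
  expect_equal(est2$onset_time, ts[brute])
  expect_equal(est2$onset_time, 2.75)

  # lookback window: a step older than the lookback horizon is ignored
  est3 <- detect_onset(fr, response_time = 5, threshold = 5, lookback_s = 1)
  expect_equal(est3$source, "none")
})

test_that("fallback and error paths follow the stated rules", {
  ts <- seq(0, 3, by = 0.25)
  fr <- mk_frames(ts, rep(60, length(ts)))
  # no supra-threshold change: previous onset is reused
  est <- detect_onset(fr, response_time = 2.6, threshold = 5,
                      previous_onset = 0.75)
  expect_equal(est$source, "fallback_previous")
  expect_equal(est$onset_time, 0.75)
  expect_lte(est$onset_time, 2.6) # never later than the response
  # no fallback available
  est2 <- detect_onset(fr, response_time = 2.6, threshold = 5)
  expect_equal(est2$source, "none")
  expect_true(is.na(reconstruct_rt(est2, 2.6)))
  expect_error(detect_onset(fr[0, ], 1, 5), "empty")
  expect_error(detect_onset(fr, -1, 5), "precedes")
  expect_error(detect_onset(fr, 1, 0), "threshold")
  # onset == response gives RT 0
  expect_equal(reconstruct_rt(structure(list(onset_time = 2, source = "detected",
                                             change_magnitude = 9),
                                        class = "onset_estimate"), 2), 0)
})

test_that("detection is frame-exact on simulated streams (property over seeds)", {
  for (seed in c(2, 17, 31)) {
    cfg <- sim_config(n_participants = 2, n_blocks = 1, trials_per_block = 30,
                      accuracy_range = c(0.65, 0.85), seed = seed,
                      frame_jitter_sd = 0.4, frame_step = 10, frame_rate_hz = 4)
    beh <- simulate_behaviour(cfg)
    frames <- simulate_frames(beh, cfg)
    # jitter-induced changes stay below threshold/2 while the step exceeds
    # 2x threshold, so every detection must hit the exact onset frame
    thr <- 4
    tr <- reconstruct_rts(beh$trials, frames, threshold = thr)
    tr <- merge(tr, beh$trial_info[, c("trial_id", "onset_time_s")])
    ans <- tr[!is.na(tr$response_timestamp_s), ]
    expect_true(all(ans$onset_source == "detected"))
    # detected onset = timestamp of the first frame at/after the true onset
    expected_frame_time <- vapply(seq_len(nrow(ans)), function(i) {
      fr <- frames[[as.character(ans$trial_id[i])]]
      fr$timestamp_s[min(which(fr$timestamp_s >= ans$onset_time_s[i]))]
    }, numeric(1))
    got_onset <- ans$response_timestamp_s - ans$rt_reconstructed_s
    expect_equal(got_onset, expected_frame_time, tolerance = 1e-9)
    # therefore the RT error is bounded by one frame period
    expect_lt(mean(abs(ans$rt_reconstructed_s - ans$rt_true_s)), 0.25)
  }
})

test_that("missed-character trials exercise the previous-onset fallback", {
  cfg <- sim_config(n_participants = 1, n_blocks = 1, trials_per_block = 40,
                    accuracy_range = c(0.65, 0.85), seed = 23,
                    frame_jitter_sd = 0, frame_step = 25,
                    frame_miss_fraction = 0.25)
  beh <- simulate_behaviour(cfg)
  frames <- simulate_frames(beh, cfg)
  tr <- reconstruct_rts(beh$trials, frames, threshold = 5)
  ans <- tr[!is.na(tr$response_timestamp_s), ]
  missed <- beh$trial_info$frame_missed[ans$trial_id]
  expect_true(all(ans$onset_source[!missed] == "detected"))
  # the first missed trial after a detection falls back to the previous onset
  fb <- ans[missed & ans$onset_source == "fallback_previous", ]
  expect_gt(nrow(fb), 0)
  for (i in seq_len(nrow(fb))) {
    prev_detected <- ans[ans$trial_id < fb$trial_id[i] &
                           ans$onset_source == "detected", ]
    prev_onset <- prev_detected$response_timestamp_s -
      prev_detected$rt_reconstructed_s
    expect_equal(fb$response_timestamp_s[i] - fb$rt_reconstructed_s[i],
                 max(prev_onset))
  }
})

test_that("auto-threshold separates jitter from steps", {
  cfg <- sim_config(n_participants = 1, n_blocks = 1, trials_per_block = 30,
                    accuracy_range = c(0.65, 0.85), seed = 29,
                    frame_jitter_sd = 0.5, frame_step = 20)
  beh <- simulate_behaviour(cfg)
  frames <- simulate_frames(beh, cfg)
  thr <- auto_threshold(frames)
  expect_gt(thr, 1e-3)
  expect_lt(thr, 20)
  tr <- reconstruct_rts(beh$trials, frames) # NULL threshold -> auto
  expect_true(all(tr$onset_source[!is.na(tr$response_timestamp_s)] == "detected"))
})
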