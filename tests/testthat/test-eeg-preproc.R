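# Preprocessing chain: band-pass behaviour, ocular regression, epoch
# extraction arithmetic, and the detrend/low-pass/decimate/trim conditioner.

test_that("band-pass preserves 10 Hz, rejects DC, attenuates 50 Hz by 20 dB", {
  eeg <- sinusoid_eeg(c(10, 0, 50), fs = 2048, dur = 8)
  out <- bandpass_continuous(eeg, 0.15, 40)
  a10 <- mid_amplitude(out$samples[1, ], 2048)
  expect_lt(abs(a10 - 1), 0.05)
  expect_lt(max(abs(out$samples[2, 2048:(7 * 2048)])), 1e-6) # DC gone
  a50 <- mid_amplitude(out$samples[3, ], 2048)
  expect_lt(a50, 10^(-20 / 20))
  expect_error(bandpass_continuous(eeg, 40, 0.15), "band edges")
})

test_that("ocular regression inverts a constructed contamination exactly", {
  fs <- 256
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  n <- length(t)
  set.seed(1)
  v_half <- 40 * sin(2 * pi * 0.7 * t)^8 # blink-like reference component
  clean <- rbind(sin(2 * pi * 9 * t), sin(2 * pi * 5 * t + 1),
                 rnorm(n), rnorm(n))
  # orthogonalize the clean signals against the reference: the regression
  # can only recover components uncorrelated with v
  v_ref <- 2 * v_half
  for (k in 1:4)
    clean[k, ] <- clean[k, ] - cov(clean[k, ], v_ref) / var(v_ref) * v_ref
  gam <- c(0.9, 0.5, -0.3, 0.2)
  # build Fp1/F1/Fp2/F2 so that mean(Fp1-F1, Fp2-F2) == 2*v_half, plus two
  # ordinary channels contaminated by it
  chans <- rbind(clean[1, ] + 2 * v_half, clean[1, ],     # Fp1, F1
                 clean[2, ] + 2 * v_half, clean[2, ],     # Fp2, F2
                 clean[3, ] + gam[3] * 2 * v_half,
                 clean[4, ] + gam[4] * 2 * v_half)
  eeg <- continuous_eeg(chans, fs, c("Fp1", "F1", "Fp2", "F2", "C3", "C4"))
  out <- remove_ocular(eeg)
  v <- 2 * v_half
  # every output channel is uncorrelated with the reference
  for (ch in seq_len(6))
    expect_lt(abs(cor(out$samples[ch, ], v)), 1e-6)
  # the ordinary channels recover their clean signal up to a DC offset
  for (k in 3:4) {
    resid <- out$samples[k + 2, ] - clean[k, ]
    expect_lt(max(abs(resid - mean(resid))), 1e-6)
  }
  # flat reference: output equals input
  eeg0 <- continuous_eeg(rbind(clean, clean[1:2, ]), fs,
                         c("C1", "C2", "C3", "C4", "F1", "F2"))
  eeg0$channel_names <- c("Fp1", "F1", "Fp2", "F2", "C3", "C4")
  eeg0$samples[1, ] <- eeg0$samples[2, ] # Fp1 == F1
  eeg0$samples[3, ] <- eeg0$samples[4, ] # Fp2 == F2
  expect_equal(remove_ocular(eeg0)$samples, eeg0$samples)
  expect_error(remove_ocular(sinusoid_eeg(c(1, 2), fs = 256)), "missing channels")
})

test_that("epoch extraction window arithmetic matches the stated design", {
  fs <- 2048
  eeg <- sinusoid_eeg(c(3, 7), fs = fs, dur = 12)
  ep <- extract_epochs(eeg, response_times = c(10, 5.5), trial_ids = c(1, 2))
  n <- dim(ep$data)[3]
  # 1900 ms duration at the native rate (to one sample)
  expect_equal((n - 1) / fs, 1.9, tolerance = 1 / fs)
  # response at t = 10 s: epoch covers [8.3, 10.2] s
  start_s <- 10 - round(1.7 * fs) / fs
  end_s <- 10 + round(0.2 * fs) / fs
  expect_equal(start_s, 8.3, tolerance = 1e-3)
  expect_equal(end_s, 10.2, tolerance = 1e-3)
  expect_equal(ep$window_ms, c(-1700, 200))
  # the stored samples really are the recording slice
  i0 <- round((10 - 1.7) * fs) + 1
  expect_equal(ep$data[1, 1, ], eeg$samples[1, i0:(i0 + n - 1)])

  # zero responses -> empty epoch set; out-of-bounds responses are skipped
  ep0 <- extract_epochs(eeg, numeric(0))
  expect_equal(dim(ep0$data)[1], 0)
  expect_warning(ep1 <- extract_epochs(eeg, c(0.5, 10)), "outside recording")
  expect_equal(ep1$trial_ids, 2L)
})

test_that("condition_epochs meets the 32 Hz / 48-sample / [-1500, 0] contract", {
  fs <- 128
  n <- round(1.7 * fs) + round(0.2 * fs) + 1
  resp <- round(1.7 * fs) + 1
  tt <- (seq_len(n) - resp) / fs
  # trials: a pure linear ramp, an 8 Hz tone, and a 20 Hz tone
  mk <- function(x) array(rep(x, each = 2), dim = c(1, 2, n))
  ramp <- mk(5 + 3 * seq_len(n))
  tone8 <- mk(sin(2 * pi * 8 * tt))
  tone20 <- mk(sin(2 * pi * 20 * tt))
  eps <- epoch_set(abind3(ramp, tone8, tone20), fs = fs,
                   window_ms = c(-1700, 200), trial_ids = 1:3,
                   channel_names = c("A", "B"))
  out <- condition_epochs(eps)
  expect_equal(out$fs, 32)
  expect_equal(dim(out$data)[3], 48)
  expect_equal(out$window_ms, c(-1500, 0))
  times <- epoch_times_ms(out)
  expect_equal(times[48], 0)            # retained window ends at the response
  expect_equal(times[1], -47 / 32 * 1000)
  # linear ramp vanishes after detrending
  expect_lt(max(abs(out$data[1, , ])), 1e-8)
  # 8 Hz survives (compare mid-window amplitude); 20 Hz is crushed to the
  # filter's stopband floor away from the reflection-padding transients
  # (the sharp stage's half-length reaches ~14 samples into the window)
  mid <- 16:40
  expect_gt(max(abs(out$data[2, 1, mid])), 0.8)
  expect_lt(max(abs(out$data[3, 1, mid])), 0.02)
  expect_error(condition_epochs(epoch_set(ramp, fs = 100,
                                          window_ms = c(-1700, 200),
                                          trial_ids = 1)),
               "multiple of 32")
})

test_that("shape invariant holds across raw rates", {
  for (fs in c(64, 128, 256)) {
    cfg <- sim_config(n_participants = 1, n_blocks = 1, trials_per_block = 24,
                      accuracy_range = c(0.65, 0.75), fs_raw = fs,
                      n_channels = 16, seed = 4)
    beh <- simulate_behaviour(cfg)
    out <- condition_epochs(simulate_epochs(beh, cfg)[[1]])
    expect_equal(dim(out$data)[2:3], c(16, 48))
    expect_equal(out$fs, 32)
  }
})
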