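# Filter design and zero-phase application.
#
# Nothing here depends on epoch semantics: these are plain DSP primitives used
# by the preprocessing module. Two designs are provided:
#   * Butterworth biquad cascades (low/high-pass), applied forward-backward
#     (filtfilt) for the band-pass of continuous EEG;
#   * Parks-McClellan (Remez exchange) equiripple linear-phase FIR low-pass,
#     used as the anti-alias filter before decimating epochs to 32 Hz.
# Both are verified in tests against their measured frequency responses.

#' Design a Butterworth filter as second-order sections
#'
#' @param n filter order (number of analog prototype poles).
#' @param cutoff_hz -3 dB cutoff frequency in Hz.
#' @param fs sampling rate in Hz.
#' @param type `"low"` or `"high"`.
#' @return numeric matrix with one row per biquad and columns
#'   `b0,b1,b2,a0,a1,a2`.
#' @export
butter_sos <- function(n, cutoff_hz, fs, type = c("low", "high")) {
  type <- match.arg(type)
  if (n < 1 || cutoff_hz <= 0 || cutoff_hz >= fs / 2)
    stop_param("invalid Butterworth specification (n=%d, cutoff=%g, fs=%g)",
               n, cutoff_hz, fs)
  # analog prototype poles on the unit circle, left half-plane
  k <- seq_len(n)
  p <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  warped <- 2 * fs * tan(pi * cutoff_hz / fs)
  if (type == "low") {
    p <- p * warped
    z <- rep(complex(real = -Inf), 0) # zeros at infinity -> z = -1 after bilinear
  } else {
    p <- warped / p
    z <- rep(complex(real = 0), n)    # zeros at s = 0 -> z = +1
  }
  # bilinear transform
  pd <- (2 * fs + p) / (2 * fs - p)
  zd <- if (length(z)) (2 * fs + z) / (2 * fs - z) else complex(0)
  zd <- c(zd, rep(-1 + 0i, n - length(zd))) # zeros at infinity map to z = -1

  # pair into biquads; poles come in conjugate pairs (plus one real for odd n)
  ord <- order(abs(Im(pd)) > 1e-12, decreasing = TRUE) # conj pairs first
  pd <- pd[ord]
  nsec <- ceiling(n / 2)
  sos <- matrix(0, nsec, 6)
  zref <- if (type == "low") 1 + 0i else -1 + 0i # unit-gain reference point
  pi_ <- 1L
  zi_ <- 1L
  for (s in seq_len(nsec)) {
    if (pi_ + 1L <= n && abs(Im(pd[pi_])) > 1e-12) {
      pp <- c(pd[pi_], Conj(pd[pi_])); pi_ <- pi_ + 2L
    } else {
      pp <- pd[pi_]; pi_ <- pi_ + 1L
    }
    nz <- length(pp)
    zz <- zd[zi_:(zi_ + nz - 1L)]; zi_ <- zi_ + nz
    b <- if (nz == 2) c(1, -Re(zz[1] + zz[2]), Re(zz[1] * zz[2])) else c(1, -Re(zz), 0)
    a <- if (nz == 2) c(1, -Re(pp[1] + pp[2]), Re(pp[1] * pp[2])) else c(1, -Re(pp), 0)
    g <- abs(sum(a * zref^(0:2)) / sum(b * zref^(0:2)))
    sos[s, ] <- c(b * g, a)
  }
  sos
}

#' Zero-phase filtering with a biquad cascade (filtfilt)
#'
#' Applies the cascade forward and backward with odd-reflection edge padding,
#' giving zero phase distortion and squared magnitude response.
#'
#' @param sos matrix from [butter_sos()].
#' @param x numeric vector or samples-by-channels matrix.
#' @param padlen reflection pad length in samples (clipped to `n - 1`).
#' @return filtered data, same shape as `x`.
#' @export
sosfiltfilt <- function(sos, x, padlen = NULL) {
  if (is.matrix(x)) return(apply(x, 2, function(col) sosfiltfilt(sos, col, padlen)))
  n <- length(x)
  padlen <- min(n - 1L, padlen %||% (3L * 20L * nrow(sos)))
  xp <- c(2 * x[1] - x[(padlen + 1):2], x, 2 * x[n] - x[(n - 1):(n - padlen)])
  y <- .sosfilt_cpp(sos, xp)
  y <- rev(.sosfilt_cpp(sos, rev(y)))
  y[(padlen + 1):(padlen + n)]
}

#' Frequency response of a biquad cascade
#'
#' @param sos matrix from [butter_sos()].
#' @param f frequencies (Hz) at which to evaluate.
#' @param fs sampling rate (Hz).
#' @return complex response (single pass; filtfilt squares the magnitude).
#' @export
sos_freqz <- function(sos, f, fs) {
  z <- exp(-2i * pi * f / fs)
  h <- rep(1 + 0i, length(f))
  for (s in seq_len(nrow(sos))) {
    b <- sos[s, 1:3]; a <- sos[s, 4:6]
    h <- h * (b[1] + b[2] * z + b[3] * z^2) / (a[1] + a[2] * z + a[3] * z^2)
  }
  h
}

#' Amplitude response of a linear-phase FIR filter
#'
#' @param h filter taps.
#' @param f frequencies (Hz).
#' @param fs sampling rate (Hz).
#' @return real amplitude (can be negative in stopband lobes of the
#'   zero-phase amplitude function); take `abs()` for magnitude.
#' @export
fir_freqz <- function(h, f, fs) {
  n <- length(h)
  m <- (n - 1) / 2
  # zero-phase amplitude: sum h[k] cos(2 pi f (k - m) / fs)
  k <- seq_len(n) - 1
  vapply(f, function(fi) sum(h * cos(2 * pi * fi * (k - m) / fs)), numeric(1))
}

# ---------------------------------------------------------------------------
# Parks-McClellan (Remez exchange) equiripple FIR low-pass, type I (odd taps).
# ---------------------------------------------------------------------------

#' Equiripple FIR low-pass design by the Remez exchange algorithm
#'
#' Type-I (odd-length, symmetric) linear-phase low-pass with passband
#' `[0, f_pass]` and stopband `[f_stop, fs/2]`. The relative band weights are
#' `1` (pass) and `w_stop` (stop), so the achieved ripples satisfy
#' `delta_pass = w_stop * delta_stop`.
#'
#' @param n_taps odd number of taps.
#' @param f_pass,f_stop band edges in Hz, `0 < f_pass < f_stop < fs/2`.
#' @param fs sampling rate in Hz.
#' @param w_stop stopband/passband weight ratio.
#' @param grid_density grid points per extremal frequency.
#' @return numeric vector of taps (symmetric, length `n_taps`).
#' @export
remez_lowpass <- function(n_taps, f_pass, f_stop, fs, w_stop = 1,
                          grid_density = 16) {
  if (n_taps %% 2 == 0) n_taps <- n_taps + 1L
  if (!(0 < f_pass && f_pass < f_stop && f_stop < fs / 2))
    stop_param("invalid band edges (pass=%g, stop=%g, fs=%g)", f_pass, f_stop, fs)
  m <- (n_taps - 1L) %/% 2L
  r <- m + 2L # number of extremal frequencies

  fp <- f_pass / fs; fstp <- f_stop / fs # normalized to [0, 0.5]
  bands <- rbind(c(0, fp), c(fstp, 0.5))
  widths <- bands[, 2] - bands[, 1]
  ngrid <- max(grid_density * r, 512L)
  npts <- pmax(8L, round(ngrid * widths / sum(widths)))
  grid <- c(seq(bands[1, 1], bands[1, 2], length.out = npts[1]),
            seq(bands[2, 1], bands[2, 2], length.out = npts[2]))
  des <- c(rep(1, npts[1]), rep(0, npts[2]))
  wt <- c(rep(1, npts[1]), rep(w_stop, npts[2]))
  ng <- length(grid)

  ext <- round(seq(1, ng, length.out = r))

  barycentric <- function(xe, ce, x) {
    # second-form barycentric interpolation with log-scaled weights
    r <- length(xe)
    logw <- numeric(r); sgn <- numeric(r)
    for (k in seq_len(r)) {
      d <- xe[k] - xe[-k]
      logw[k] <- -sum(log(abs(d)))
      sgn[k] <- prod(sign(d))
    }
    logw <- logw - max(logw)
    wk <- sgn * exp(logw)
    out <- numeric(length(x))
    for (i in seq_along(x)) {
      d <- x[i] - xe
      hit <- which(abs(d) < 1e-13)
      if (length(hit)) { out[i] <- ce[hit[1]]; next }
      t <- wk / d
      out[i] <- sum(t * ce) / sum(t)
    }
    out
  }

  xg <- cos(2 * pi * grid)
  delta <- 0
  for (iter in 1:60) {
    xe <- xg[ext]
    de <- des[ext]; we <- wt[ext]
    rr <- length(ext)
    logw <- numeric(rr); sgn <- numeric(rr)
    for (k in seq_len(rr)) {
      d <- xe[k] - xe[-k]
      logw[k] <- -sum(log(abs(d)))
      sgn[k] <- prod(sign(d))
    }
    logw <- logw - max(logw)
    ak <- sgn * exp(logw)
    alt <- (-1)^(seq_len(rr) - 1)
    delta <- sum(ak * de) / sum(ak * alt / we)
    ce <- de - alt * delta / we
    A <- barycentric(xe, ce, xg)
    E <- wt * (A - des)

    # locate alternating extrema of the weighted error
    cand <- c(1L)
    if (ng > 2) {
      dE <- diff(E)
      int <- which(dE[-1] * dE[-length(dE)] <= 0) + 1L
      cand <- c(cand, int)
    }
    cand <- sort(unique(c(cand, npts[1], npts[1] + 1L, ng)))
    # enforce alternation: among consecutive same-sign candidates keep largest
    keep <- integer(0)
    for (i in cand) {
      if (!length(keep)) { keep <- i; next }
      last <- keep[length(keep)]
      if (sign(E[i]) == sign(E[last]) || E[i] == 0) {
        if (abs(E[i]) > abs(E[last])) keep[length(keep)] <- i
      } else keep <- c(keep, i)
    }
    # reduce to exactly r extremals
    while (length(keep) > r) {
      if (length(keep) - r == 1L) {
        drop <- if (abs(E[keep[1]]) < abs(E[keep[length(keep)]])) 1L else length(keep)
        keep <- keep[-drop]
      } else {
        j <- which.min(abs(E[keep]))
        keep <- keep[-j]
        # restore alternation after removal
        i <- 2L
        while (i <= length(keep)) {
          if (sign(E[keep[i]]) == sign(E[keep[i - 1]])) {
            drop <- if (abs(E[keep[i]]) < abs(E[keep[i - 1]])) i else i - 1L
            keep <- keep[-drop]
          } else i <- i + 1L
        }
      }
    }
    if (length(keep) < r) { # pathological; pad with largest remaining errors
      pool <- setdiff(order(abs(E), decreasing = TRUE), keep)
      keep <- sort(c(keep, pool[seq_len(r - length(keep))]))
    }
    new_ext <- sort(keep)
    conv <- max(abs(E[new_ext])) - abs(delta)
    ext <- new_ext
    if (is.finite(conv) && conv < 1e-6 * max(abs(delta), 1e-12)) break
  }

  # impulse response via inverse DFT of the amplitude samples
  xe <- xg[ext]
  de <- des[ext]; we <- wt[ext]
  rr <- length(ext)
  alt <- (-1)^(seq_len(rr) - 1)
  ce <- de - alt * delta / we
  fsamp <- (0:m) / n_taps
  Asamp <- barycentric(xe, ce, cos(2 * pi * fsamp))
  h <- numeric(n_taps)
  idx <- 0:(n_taps - 1)
  for (nn in idx) {
    h[nn + 1] <- (Asamp[1] +
      2 * sum(Asamp[-1] * cos(2 * pi * (1:m) * (nn - m) / n_taps))) / n_taps
  }
  h
}

#' Design an equiripple low-pass meeting ripple/attenuation targets
#'
#' Estimates the required order (Kaiser's formula), designs with
#' [remez_lowpass()], measures the achieved response and increases the order
#' until the passband ripple and stopband attenuation targets are met.
#'
#' @param f_pass,f_stop band edges (Hz).
#' @param fs sampling rate (Hz).
#' @param ripple_db maximum peak-to-peak passband ripple (dB).
#' @param atten_db minimum stopband attenuation (dB).
#' @return list with `taps`, `achieved_ripple_db`, `achieved_atten_db`,
#'   `n_taps`.
#' @export
design_lowpass_fir <- function(f_pass, f_stop, fs, ripple_db = 1,
                               atten_db = 40) {
  dp <- (10^(ripple_db / 40) - 1) / (10^(ripple_db / 40) + 1)
  ds <- 10^(-atten_db / 20)
  df <- (f_stop - f_pass) / fs
  n <- ceiling((-20 * log10(sqrt(dp * ds)) - 13) / (14.6 * df) + 1)
  n <- max(11L, as.integer(n))
  if (n %% 2 == 0) n <- n + 1L
  for (try in 1:8) {
    h <- remez_lowpass(n, f_pass, f_stop, fs, w_stop = dp / ds)
    fgrid_p <- seq(0, f_pass, length.out = 400)
    fgrid_s <- seq(f_stop, fs / 2, length.out = 800)
    ap <- fir_freqz(h, fgrid_p, fs)
    as_ <- abs(fir_freqz(h, fgrid_s, fs))
    rip <- 20 * log10(max(ap) / min(ap))
    att <- -20 * log10(max(as_))
    if (is.finite(rip) && is.finite(att) && min(ap) > 0 &&
        rip <= ripple_db && att >= atten_db)
      return(list(taps = h, achieved_ripple_db = rip, achieved_atten_db = att,
                  n_taps = n))
    n <- n + 2L * max(1L, ceiling(n * 0.06))
    if (n %% 2 == 0) n <- n + 1L
  }
  stop_param("equiripple design failed to meet %g dB ripple / %g dB attenuation",
             ripple_db, atten_db)
}

# (zero-phase FIR application lives in the compiled .fir_decim_cpp kernel,
# which fuses the group-delay-compensated convolution with decimation)
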