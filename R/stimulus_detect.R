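# Stimulus-onset reconstruction from frame streams: backward search from the
# response for a supra-threshold inter-frame change in mean RGB, with a
# previous-onset fallback when the detector misses the character.

frame_change <- function(frames, metric = c("pooled", "per_channel")) {
  metric <- match.arg(metric)
  rgb <- as.matrix(frames[, c("mean_r", "mean_g", "mean_b")])
  if (metric == "pooled") {
    m <- rowMeans(rgb)
    c(NA_real_, abs(diff(m)))
  } else {
    c(NA_real_, apply(abs(diff(rgb)), 1, max))
  }
}

#' Auto-calibrate the onset-detection threshold
#'
#' Robust threshold `median + k * MAD` of the pooled inter-frame changes over
#' a reference stream (scene-brightness invariant).
#'
#' @param frames a frame-stream data frame (or list of them, pooled).
#' @param k MAD multiplier.
#' @return threshold in mean-RGB units.
#' @export
auto_threshold <- function(frames, k = 8) {
  if (is.data.frame(frames)) frames <- list(frames)
  ch <- unlist(lapply(frames, function(f) frame_change(f)[-1]))
  median(ch) + k * mad(ch)
}

#' Detect the stimulus onset preceding a response
#'
#' Scans frames backward from the last frame at or before `response_time`
#' (within `lookback_s`) and returns the most recent frame whose mean-RGB
#' change versus its predecessor exceeds `threshold`. If no frame qualifies,
#' the previous trial's onset is used as fallback; with no fallback the
#' estimate is `none`.
#'
#' @param frames frame-stream data frame with columns `timestamp_s`,
#'   `mean_r`, `mean_g`, `mean_b`.
#' @param response_time absolute response timestamp (s).
#' @param threshold positive change threshold (mean-RGB units).
#' @param previous_onset onset time of the previous stimulus (s) or `NULL`.
#' @param lookback_s how far before the response to scan (defaults to the
#'   2.5 s response deadline).
#' @param metric `"pooled"` thresholds the change of the grand mean over RGB
#'   channels; `"per_channel"` thresholds the max per-channel change.
#' @return object of class `onset_estimate`: `onset_time`, `source`
#'   (`detected`, `fallback_previous` or `none`), `change_magnitude`.
#' @export
detect_onset <- function(frames, response_time, threshold,
                         previous_onset = NULL, lookback_s = 2.5,
                         metric = c("pooled", "per_channel")) {
  if (!nrow(frames)) stop_param("empty frame stream")
  if (threshold <= 0) stop_param("threshold must be positive")
  ts <- frames$timestamp_s
  if (response_time < ts[1])
    stop_param("response (%g s) precedes the first frame (%g s)",
               response_time, ts[1])
  last <- max(which(ts <= response_time))
  first <- if (is.finite(lookback_s))
    min(which(ts >= response_time - lookback_s)) else 1L
  chg <- frame_change(frames, metric)
  est <- NULL
  lo <- max(first, 2L)
  if (last >= lo) {
    for (i in rev(seq(lo, last))) {
      if (!is.na(chg[i]) && chg[i] > threshold) {
        est <- list(onset_time = ts[i], source = "detected",
                    change_magnitude = chg[i])
        break
      }
    }
  }
  if (is.null(est)) {
    est <- if (!is.null(previous_onset) && !is.na(previous_onset)) {
      list(onset_time = min(previous_onset, response_time),
           source = "fallback_previous", change_magnitude = NA_real_)
    } else {
      list(onset_time = NA_real_, source = "none",
           change_magnitude = NA_real_)
    }
  }
  structure(est, class = "onset_estimate")
}

#' Reconstruct a response time from an onset estimate
#'
#' @param onset an `onset_estimate` from [detect_onset()].
#' @param response_time absolute response timestamp (s).
#' @return RT in seconds, or `NA` when the onset is absent.
#' @export
reconstruct_rt <- function(onset, response_time) {
  stopifnot(inherits(onset, "onset_estimate"))
  if (onset$source == "none" || is.na(onset$onset_time)) return(NA_real_)
  response_time - onset$onset_time
}

#' Reconstruct RTs for a whole dataset
#'
#' Runs [detect_onset()] per trial per participant, carrying the most recent
#' detected onset forward as the fallback (trial order), and appends a
#' `rt_reconstructed_s` column to the trial table.
#'
#' @param trials trial table (see [write_trials()] for columns).
#' @param frames named list of frame streams keyed by trial id.
#' @param threshold change threshold; `NULL` auto-calibrates per stream set
#'   via [auto_threshold()].
#' @param lookback_s backward scan horizon (s).
#' @return `trials` with `rt_reconstructed_s` (and `onset_source`) added.
#' @export
reconstruct_rts <- function(trials, frames, threshold = NULL,
                            lookback_s = 2.5) {
  if (is.null(threshold)) threshold <- auto_threshold(frames)
  trials$rt_reconstructed_s <- NA_real_
  trials$onset_source <- NA_character_
  for (pid in unique(trials$participant_id)) {
    rows <- which(trials$participant_id == pid)
    rows <- rows[order(trials$trial_id[rows])]
    prev <- NULL
    for (i in rows) {
      rt_s <- trials$response_timestamp_s[i]
      if (is.na(rt_s)) next
      fr <- frames[[as.character(trials$trial_id[i])]]
      est <- detect_onset(fr, rt_s, threshold, previous_onset = prev,
                          lookback_s = lookback_s)
      trials$rt_reconstructed_s[i] <- reconstruct_rt(est, rt_s)
      trials$onset_source[i] <- est$source
      if (est$source == "detected") prev <- est$onset_time
    }
  }
  trials
}
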