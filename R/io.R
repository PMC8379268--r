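# File formats: trial-table CSV, frame-stream CSV, a plain-text epoch
# container (meta.json + per-participant CSV matrices), and a minimal
# continuous BDF/EDF reader for real recordings. All formats round-trip and
# are documented here; missing values are empty CSV fields.

trial_columns <- c("participant_id", "block", "trial_id", "true_label",
                   "decision", "response_timestamp_s", "reported_confidence",
                   "confidence_timestamp_s", "correctness")

validate_trials <- function(tr, deadline_rule = FALSE) {
  bad <- !is.na(tr$reported_confidence) &
    (tr$reported_confidence %% 10 != 0 | tr$reported_confidence < 0 |
       tr$reported_confidence > 100)
  if (any(bad))
    stop_param("reported_confidence off the 0,10,...,100 grid at row(s) %s",
               paste(head(which(bad), 5), collapse = ", "))
  both <- !is.na(tr$confidence_timestamp_s) & !is.na(tr$response_timestamp_s)
  if (any(tr$confidence_timestamp_s[both] < tr$response_timestamp_s[both]))
    stop_param("confidence timestamp precedes response timestamp")
  if (any(!tr$decision %in% c(-1L, 1L) & !is.na(tr$decision)))
    stop_param("decision must be -1, +1 or missing")
  # derive correctness where absent
  need <- is.na(tr$correctness) & tr$true_label != 0L
  derived <- ifelse(is.na(tr$decision),
                    if (deadline_rule) "incorrect" else NA_character_,
                    ifelse(tr$decision == tr$true_label, "correct", "incorrect"))
  tr$correctness[need] <- derived[need]
  tr
}

#' Write / read the trial table CSV
#'
#' One row per participant x trial with the fixed column set
#' `participant_id, block, trial_id, true_label, decision,
#' response_timestamp_s, reported_confidence, confidence_timestamp_s,
#' correctness`. Missing values are empty fields; reported confidence must
#' sit on the 0--100 step-10 grid. Reading validates the header and rows and
#' derives `correctness` where absent (a missing decision is labelled
#' incorrect only under `deadline_rule = TRUE`, the outpost-style
#' no-response rule).
#'
#' @param trials trial table data frame (extra columns are dropped on write).
#' @param path CSV file path.
#' @return `write_trials` returns `path` invisibly; `read_trials` the
#'   validated data frame.
#' @export
write_trials <- function(trials, path) {
  miss <- setdiff(trial_columns, names(trials))
  if (length(miss))
    stop_param("trial table lacks column(s): %s", paste(miss, collapse = ", "))
  write.csv(trials[trial_columns], path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trials
#' @param deadline_rule label missing decisions as incorrect (outpost rule).
#' @export
read_trials <- function(path, deadline_rule = FALSE) {
  hdr <- gsub('"', "", strsplit(readLines(path, n = 1L), ",")[[1]])
  if (!identical(hdr, trial_columns))
    stop_param("unexpected trial CSV header: %s", paste(hdr, collapse = ","))
  tr <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(participant_id = "character",
                                correctness = "character"))
  tr$correctness[tr$correctness == ""] <- NA_character_
  for (line in which(is.na(tr$trial_id) | is.na(tr$true_label)))
    stop_param("malformed trial row at line %d", line + 1L)
  validate_trials(tr, deadline_rule)
}

#' Write / read frame streams
#'
#' One CSV per trial with columns `frame_index, timestamp_s, mean_r, mean_g,
#' mean_b`.
#'
#' @param frames named list of frame-stream data frames (names = trial ids).
#' @param dir directory for the per-trial CSVs.
#' @return `write_frames` returns `dir` invisibly; `read_frames` the named
#'   list.
#' @export
write_frames <- function(frames, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(frames))
    write.csv(frames[[id]], file.path(dir, sprintf("trial_%s.csv", id)),
              row.names = FALSE)
  invisible(dir)
}

#' @rdname write_frames
#' @export
read_frames <- function(dir) {
  files <- list.files(dir, pattern = "^trial_.*\\.csv$", full.names = TRUE)
  ids <- sub("^trial_(.*)\\.csv$", "\\1", basename(files))
  out <- lapply(files, read.csv, stringsAsFactors = FALSE)
  names(out) <- ids
  out[order(as.numeric(ids))]
}

#' Write / read the epoch container
#'
#' A plain-text directory layout: `meta.json` holds `fs`, `window_ms`,
#' `channel_names` and per-participant `trial_ids`/`labels`; each
#' participant's data sits in `<id>_data.csv` with `trials * channels` rows
#' (trial-major) and one column per sample.
#'
#' @param epochs_list named list of [epoch_set()]s by participant id.
#' @param dir container directory.
#' @param digits significant digits kept on write.
#' @return `write_epochs` returns `dir` invisibly; `read_epochs` the named
#'   list of epoch sets.
#' @export
write_epochs <- function(epochs_list, dir, digits = 6) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list()
  for (pid in names(epochs_list)) {
    ep <- epochs_list[[pid]]
    d <- dim(ep$data)
    meta[[pid]] <- list(fs = ep$fs, window_ms = ep$window_ms,
                        channel_names = ep$channel_names,
                        trial_ids = ep$trial_ids, labels = ep$labels,
                        dim = d)
    flat <- matrix(aperm(ep$data, c(3, 2, 1)), nrow = d[3]) # samples x (ch*trial)
    write.table(signif(t(flat), digits),
                file.path(dir, paste0(pid, "_data.csv")),
                sep = ",", row.names = FALSE, col.names = FALSE)
  }
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  out <- list()
  for (pid in names(meta)) {
    mm <- meta[[pid]]
    d <- as.integer(mm$dim)
    x <- as.matrix(read.csv(file.path(dir, paste0(pid, "_data.csv")),
                            header = FALSE))
    if (!all(dim(x) == c(d[1] * d[2], d[3])))
      stop_param("epoch data shape mismatch for %s", pid)
    dat <- aperm(array(t(x), dim = c(d[3], d[2], d[1])), c(3, 2, 1))
    out[[pid]] <- epoch_set(dat, fs = mm$fs, window_ms = mm$window_ms,
                            trial_ids = mm$trial_ids, labels = mm$labels,
                            channel_names = mm$channel_names,
                            participant = pid)
  }
  out
}

# --------------------------------------------------------------------------
# Minimal continuous BDF (24-bit) / EDF (16-bit) reader. The layout is a
# fixed 256-byte ASCII header plus 256 bytes per signal, then interleaved
# data records. Annotations and discontinuous files are not supported.
# --------------------------------------------------------------------------

read_ascii <- function(con, n) trimws(rawToChar(readBin(con, "raw", n)))

#' Read a continuous BDF or EDF recording
#'
#' Supports the plain continuous variants (BioSemi BDF 24-bit, EDF 16-bit),
#' scaling digital values to physical units from the per-signal calibration
#' fields. All signals must share one sampling rate.
#'
#' @param path file path (`.bdf` or `.edf` by content, not extension).
#' @param channels optional subset of channel labels to keep.
#' @return a [continuous_eeg()].
#' @export
read_bdf <- function(path, channels = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 8)
  is_bdf <- magic[1] == as.raw(255)
  read_ascii(con, 80); read_ascii(con, 80) # subject / recording ids
  read_ascii(con, 8); read_ascii(con, 8)   # date / time
  header_bytes <- as.integer(read_ascii(con, 8))
  read_ascii(con, 44)
  n_records <- as.integer(read_ascii(con, 8))
  record_dur <- as.numeric(read_ascii(con, 8))
  ns <- as.integer(read_ascii(con, 4))
  labels <- vapply(seq_len(ns), function(i) read_ascii(con, 16), character(1))
  for (i in seq_len(ns)) read_ascii(con, 80) # transducer
  for (i in seq_len(ns)) read_ascii(con, 8)  # dimension
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(read_ascii(con, 8)), numeric(1))
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(read_ascii(con, 8)), numeric(1))
  dmin_ <- vapply(seq_len(ns), function(i) as.numeric(read_ascii(con, 8)), numeric(1))
  dmax_ <- vapply(seq_len(ns), function(i) as.numeric(read_ascii(con, 8)), numeric(1))
  for (i in seq_len(ns)) read_ascii(con, 80) # prefiltering
  nsamp <- vapply(seq_len(ns), function(i) as.integer(read_ascii(con, 8)), integer(1))
  for (i in seq_len(ns)) read_ascii(con, 32) # reserved
  seek(con, header_bytes)
  if (length(unique(nsamp)) != 1)
    stop_param("mixed per-signal sampling rates are not supported")
  spr <- nsamp[1]
  fs <- spr / record_dur
  gain <- (pmax_ - pmin_) / (dmax_ - dmin_)
  offset <- pmin_ - gain * dmin_

  dat <- matrix(0, ns, n_records * spr)
  for (r in seq_len(n_records)) {
    for (s in seq_len(ns)) {
      if (is_bdf) {
        raw3 <- readBin(con, "raw", 3 * spr)
        m <- matrix(as.integer(raw3), nrow = 3)
        v <- m[1, ] + 256L * m[2, ] + 65536L * m[3, ]
        v <- ifelse(v >= 8388608, v - 16777216, v)
      } else {
        v <- readBin(con, "integer", spr, size = 2, endian = "little")
      }
      dat[s, ((r - 1) * spr + 1):(r * spr)] <- gain[s] * v + offset[s]
    }
  }
  if (!is.null(channels)) {
    keep <- match(channels, labels)
    if (anyNA(keep)) stop_param("channel(s) not in file: %s",
                                paste(channels[is.na(keep)], collapse = ", "))
    dat <- dat[keep, , drop = FALSE]; labels <- labels[keep]
  }
  continuous_eeg(dat, fs = fs, channel_names = labels)
}

# Internal writer used by tests to round-trip the reader (binary fixtures
# cannot be checked in). Continuous layout, one data record per second.
write_bdf <- function(eeg, path, bdf = TRUE) {
  ns <- nrow(eeg$samples)
  fs <- eeg$fs
  n_records <- ceiling(ncol(eeg$samples) / fs)
  pad <- n_records * fs - ncol(eeg$samples)
  x <- cbind(eeg$samples, matrix(0, ns, pad))
  pmin_ <- -32768; pmax_ <- 32767
  dmin_ <- if (bdf) -8388608 else -32768
  dmax_ <- if (bdf) 8388607 else 32767
  gain <- (pmax_ - pmin_) / (dmax_ - dmin_)
  dig <- round((x - pmin_) / gain + dmin_)

  con <- file(path, "wb")
  on.exit(close(con))
  pad_field <- function(s, n) {
    s <- substr(as.character(s), 1, n)
    paste0(s, strrep(" ", n - nchar(s)))
  }
  wfield <- function(s, n) writeBin(charToRaw(pad_field(s, n)), con)
  if (bdf) {
    writeBin(as.raw(255), con); wfield("BIOSEMI", 7)
  } else wfield("0", 8)
  wfield("synthetic subject", 80); wfield("synthetic recording", 80)
  wfield("01.01.20", 8); wfield("00.00.00", 8)
  wfield(256 * (1 + ns), 8)
  wfield(if (bdf) "24BIT" else "EDF", 44)
  wfield(n_records, 8); wfield("1", 8); wfield(ns, 4)
  for (l in eeg$channel_names) wfield(l, 16)
  for (i in seq_len(ns)) wfield("synthetic", 80)
  for (i in seq_len(ns)) wfield("uV", 8)
  for (i in seq_len(ns)) wfield(pmin_, 8)
  for (i in seq_len(ns)) wfield(pmax_, 8)
  for (i in seq_len(ns)) wfield(dmin_, 8)
  for (i in seq_len(ns)) wfield(dmax_, 8)
  for (i in seq_len(ns)) wfield("none", 80)
  for (i in seq_len(ns)) wfield(fs, 8)
  for (i in seq_len(ns)) wfield("", 32)
  for (r in seq_len(n_records)) {
    for (s in seq_len(ns)) {
      v <- as.integer(dig[s, ((r - 1) * fs + 1):(r * fs)])
      if (bdf) {
        v <- ifelse(v < 0, v + 16777216L, v)
        b <- rbind(v %% 256L, (v %/% 256L) %% 256L, (v %/% 65536L) %% 256L)
        writeBin(as.raw(b), con)
      } else {
        writeBin(v, con, size = 2, endian = "little")
      }
    }
  }
  invisible(path)
}
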