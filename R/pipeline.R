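# End-to-end orchestration: simulate (or accept) a dataset, reconstruct RTs
# from the frame streams, condition epochs, fit the four confidence
# estimators per participant, and assemble the trial x participant matrices
# that the group and anytime layers consume.

#' Run the full cBCI pipeline on a synthetic experiment
#'
#' Simulates behaviour, frames and epochs under `config`, reconstructs RTs by
#' backward frame differencing (auto-calibrated threshold), conditions the
#' epochs to 32 Hz / `[-1500, 0]` ms, and fits the four study estimators
#' (`rt`, `rt+conf`, `nf+rt`, `nf+rt+conf`) per participant with
#' cross-validated random forests. Epochs are generated and conditioned one
#' participant at a time to bound memory.
#'
#' @param config a [sim_config()].
#' @param schemas schema names to fit.
#' @param seed estimator seed (folds, forests, tie-breaks); defaults to the
#'   config seed.
#' @param keep_epochs keep the conditioned epoch sets (needed for ERP
#'   analysis; modest memory at 48 samples).
#' @return object of class `cbci_run`: trial/participant matrices
#'   (`decisions`, `truth`, `resp_times`, `conf_times`, `reported_conf`),
#'   per-schema weight matrices `weights`, `estimators`,
#'   `training_accuracies`, `trials`, `rt_summary`, and optionally `epochs`.
#' @export
run_pipeline <- function(config,
                         schemas = c("rt", "rt+conf", "nf+rt", "nf+rt+conf"),
                         seed = NULL, keep_epochs = TRUE) {
  seed <- seed %||% config$seed
  beh <- simulate_behaviour(config)
  frames <- simulate_frames(beh, config)
  trials <- reconstruct_rts(beh$trials, frames)

  pids <- beh$participants$participant_id
  info <- beh$trial_info
  dec_ids <- info$trial_id[info$true_label != 0L] # decision trials
  n_dec <- length(dec_ids); n_part <- length(pids)
  mat <- function() matrix(NA_real_, n_dec, n_part,
                           dimnames = list(dec_ids, pids))
  decisions <- mat(); resp_times <- mat(); conf_times <- mat()
  reported_conf <- mat(); rt_recon <- mat(); rt_true <- mat()
  weights <- lapply(schemas, function(s) mat())
  names(weights) <- schemas
  estimators <- list(); cond_epochs <- list()

  needs_neural <- any(vapply(schemas, function(s)
    schema_from_name(s)$use_neural, logical(1)))

  for (pid in pids) {
    rows <- trials[trials$participant_id == pid, ]
    rows <- rows[match(dec_ids, rows$trial_id), ]
    decisions[, pid] <- rows$decision
    resp_times[, pid] <- rows$response_timestamp_s
    conf_times[, pid] <- rows$confidence_timestamp_s
    reported_conf[, pid] <- rows$reported_confidence
    rt_recon[, pid] <- rows$rt_reconstructed_s
    rt_true[, pid] <- rows$rt_true_s

    answered <- which(!is.na(rows$decision))
    labels <- rows$correctness[answered]
    ep <- NULL
    if (needs_neural) {
      ep <- condition_epochs(simulate_epochs(beh, config, pid)[[pid]])
      # align conditioned epochs with the answered decision trials
      stopifnot(identical(ep$trial_ids, rows$trial_id[answered]))
      if (keep_epochs) cond_epochs[[pid]] <- ep
    }
    est_p <- list()
    for (s in schemas) {
      sc <- schema_from_name(s)
      est <- fit_confidence(
        epochs = if (sc$use_neural) ep else NULL,
        rts = rows$rt_reconstructed_s[answered],
        reported_confidences = rows$reported_confidence[answered],
        labels = labels, schema = sc,
        seed = derive_seed(seed, paste0(pid, "-", s)))
      weights[[s]][answered, pid] <- est$confidences
      est_p[[s]] <- est
    }
    estimators[[pid]] <- est_p
  }

  truth <- info$true_label[match(as.integer(dec_ids), info$trial_id)]
  training_acc <- vapply(pids, function(pid) {
    rows <- trials[trials$participant_id == pid & trials$true_label != 0L, ]
    mean(rows$correctness == "correct", na.rm = TRUE)
  }, numeric(1))

  ok <- !is.na(rt_recon) & !is.na(rt_true)
  rt_summary <- list(
    mean_abs_error_s = mean(abs(rt_recon[ok] - rt_true[ok])),
    detected_fraction = mean(trials$onset_source == "detected", na.rm = TRUE))

  structure(list(config = config, trials = trials, truth = truth,
                 decisions = decisions, resp_times = resp_times,
                 conf_times = conf_times, reported_conf = reported_conf,
                 rt_reconstructed = rt_recon, rt_true = rt_true,
                 weights = weights, estimators = estimators,
                 training_accuracies = training_acc,
                 rt_summary = rt_summary,
                 epochs = if (length(cond_epochs)) cond_epochs else NULL,
                 seed = seed),
            class = "cbci_run")
}

#' Strategy accuracy tables for a pipeline run
#'
#' Evaluates the six study strategies (majority, dictator, and the four
#' confidence-weighted schemas) over all groups of the requested sizes.
#'
#' @param run a `cbci_run` from [run_pipeline()].
#' @param group_sizes sizes to evaluate.
#' @param n_boot bootstrap resamples for SEMs.
#' @param seed tie-break / bootstrap seed (defaults to the run seed).
#' @return named list of [strategy_accuracy()] tables: `majority`,
#'   `dictator`, and one per fitted schema.
#' @export
run_strategies <- function(run, group_sizes = 1:10, n_boot = 500L,
                           seed = NULL) {
  seed <- seed %||% run$seed
  out <- list(
    majority = strategy_accuracy(run$truth, run$decisions,
                                 strategy = "majority",
                                 group_sizes = group_sizes, n_boot = n_boot,
                                 seed = seed),
    dictator = strategy_accuracy(run$truth, run$decisions,
                                 strategy = "dictator",
                                 group_sizes = group_sizes,
                                 training_accuracies = run$training_accuracies,
                                 n_boot = n_boot, seed = seed))
  for (s in names(run$weights)) {
    out[[s]] <- strategy_accuracy(run$truth, run$decisions,
                                  weights = run$weights[[s]],
                                  strategy = "weighted",
                                  group_sizes = group_sizes, n_boot = n_boot,
                                  seed = seed)
  }
  out
}

#' @export
print.cbci_run <- function(x, ...) {
  cat(sprintf("cbci_run: %d participants, %d decision trials\n",
              ncol(x$decisions), nrow(x$decisions)))
  cat(sprintf("  schemas: %s\n", paste(names(x$weights), collapse = ", ")))
  cat(sprintf("  RT reconstruction: mean |error| = %.4f s (%.1f%% onsets detected)\n",
              x$rt_summary$mean_abs_error_s,
              100 * x$rt_summary$detected_fraction))
  invisible(x)
}
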