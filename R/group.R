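# Group decision formation. Votes are +1/-1 (0 = not yet decided) and the
# confidence-weighted group decision is the sign of the weighted vote sum;
# exact ties are broken by a seeded fair coin, consistent with the standard
# majority rule (the two classes are equiprobable by design).

#' Enumerate all groups of a given size
#'
#' @param n_participants pool size.
#' @param m group size.
#' @return list of sorted integer member tuples, lexicographic order,
#'   `choose(n, m)` entries.
#' @export
enumerate_groups <- function(n_participants, m) {
  if (m < 1 || m > n_participants)
    stop_param("group size %d outside 1..%d", m, n_participants)
  cols <- combn(n_participants, m)
  lapply(seq_len(ncol(cols)), function(j) cols[, j])
}

# Deterministic fair coin for tie-breaks, keyed so that the same
# (seed, trial, group) always resolves the same way in every code path.
tie_coin <- function(tie_seed) {
  with_seed(tie_seed, sample(c(-1L, 1L), 1))
}

#' Confidence-weighted group decision
#'
#' Sign of `sum(w_p * d_p)` over members. Members with no decision must carry
#' weight 0 (the pre-response convention). An exactly-zero sum is broken by a
#' seeded fair coin.
#'
#' @param decisions member decisions in `{-1, +1, 0}` (0 = no decision yet;
#'   `NA` treated as 0).
#' @param weights nonnegative member weights; must be 0 where `decisions`
#'   is 0.
#' @param tie_seed integer seed for the tie-break coin.
#' @return `-1` or `+1`, or `NA` when no member has decided.
#' @export
weighted_decision <- function(decisions, weights, tie_seed = 0L) {
  decisions[is.na(decisions)] <- 0L
  if (any(weights < 0)) stop_param("weights must be nonnegative")
  if (any(weights[decisions == 0] != 0))
    stop_param("members with no decision must have weight 0")
  if (all(decisions == 0)) return(NA_integer_)
  s <- sum(weights * decisions)
  if (s > 0) 1L else if (s < 0) -1L else tie_coin(tie_seed)
}

#' Standard majority group decision
#'
#' Unweighted vote count over members who decided; an exact tie is broken by
#' a seeded fair coin.
#'
#' @inheritParams weighted_decision
#' @return `-1` or `+1`, or `NA` when no member has decided.
#' @export
majority_decision <- function(decisions, tie_seed = 0L) {
  decisions[is.na(decisions)] <- 0L
  weighted_decision(decisions, as.numeric(decisions != 0), tie_seed)
}

#' Dictator group decision
#'
#' Returns the decision of the member with the highest training-set accuracy;
#' accuracy ties are broken in favour of the lowest member id. If the best
#' member has no decision, the next-best member decides.
#'
#' @param decisions member decisions in `{-1, +1, 0/NA}`.
#' @param training_accuracies training accuracy per member.
#' @return `-1` or `+1`, or `NA` when no member has decided.
#' @export
dictator_decision <- function(decisions, training_accuracies) {
  decisions[is.na(decisions)] <- 0L
  ord <- order(-training_accuracies, seq_along(training_accuracies))
  for (i in ord) if (decisions[i] != 0) return(as.integer(decisions[i]))
  NA_integer_
}

#' Mean group accuracy per size for a decision strategy
#'
#' Evaluates a strategy over all `choose(n, m)` groups for each requested
#' size: per group, the fraction of decision trials where the group decision
#' matches the truth (a trial where no member decided counts as incorrect,
#' the no-response rule); then the mean over groups and a bootstrap SEM over
#' group accuracies.
#'
#' @param truth per-trial true labels, `+1`/`-1`.
#' @param decisions trials x participants matrix of member decisions
#'   (`NA` = no decision).
#' @param weights trials x participants matrix of member confidences (used by
#'   `strategy = "weighted"`).
#' @param strategy `"weighted"`, `"majority"` or `"dictator"`.
#' @param group_sizes integer vector of sizes to evaluate.
#' @param training_accuracies per-participant accuracy (dictator strategy).
#' @param n_boot bootstrap resamples for the SEM.
#' @param seed seed for tie-break coins and the bootstrap.
#' @return data frame with columns `size`, `strategy`, `mean_accuracy`,
#'   `sem`, `n_groups`; attribute `group_accuracies` holds the per-group
#'   accuracy vectors by size.
#' @export
strategy_accuracy <- function(truth, decisions, weights = NULL,
                              strategy = c("weighted", "majority", "dictator"),
                              group_sizes = 1:10,
                              training_accuracies = NULL, n_boot = 1000L,
                              seed = 1L) {
  strategy <- match.arg(strategy)
  n_part <- ncol(decisions)
  n_trial <- nrow(decisions)
  if (length(truth) != n_trial) stop_param("truth/decisions mismatch")
  if (strategy == "weighted") {
    if (is.null(weights)) stop_param("weighted strategy needs weights")
    weights <- ifelse(is.na(decisions) | decisions == 0, 0, weights)
  }
  if (strategy == "dictator" && is.null(training_accuracies))
    stop_param("dictator strategy needs training accuracies")
  d0 <- decisions
  d0[is.na(d0)] <- 0L

  res <- list(); acc_by_size <- list()
  for (m in group_sizes) {
    groups <- enumerate_groups(n_part, m)
    gacc <- vapply(seq_along(groups), function(gi) {
      g <- groups[[gi]]
      dg <- d0[, g, drop = FALSE]
      s <- switch(strategy,
        weighted = rowSums(dg * weights[, g, drop = FALSE]),
        majority = rowSums(dg),
        dictator = NULL)
      if (strategy == "dictator") {
        ord <- g[order(-training_accuracies[g], g)]
        dec <- rep(NA_integer_, n_trial)
        for (p in ord) {
          fill <- is.na(dec) & d0[, p] != 0
          dec[fill] <- d0[fill, p]
        }
      } else {
        dec <- sign(s)
        ties <- which(dec == 0 & rowSums(dg != 0) > 0)
        for (i in ties)
          dec[i] <- tie_coin(derive_seed(seed, i * 1009L + gi))
        dec[rowSums(dg != 0) == 0] <- NA_integer_
      }
      mean(!is.na(dec) & dec == truth) # undecided trials count as errors
    }, numeric(1))
    sem <- bootstrap_sem(gacc, n_boot = n_boot, seed = derive_seed(seed, m))
    res[[as.character(m)]] <- data.frame(size = m, strategy = strategy,
                                         mean_accuracy = mean(gacc),
                                         sem = sem, n_groups = length(gacc))
    acc_by_size[[as.character(m)]] <- gacc
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "group_accuracies") <- acc_by_size
  out
}
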