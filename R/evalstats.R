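# Analysis machinery: two-tailed Wilcoxon signed-rank (exact with midranks
# for small n, normal approximation with tie correction otherwise), Holm
# step-down adjustment, bootstrap SEM, pointwise ERP comparisons and pairwise
# strategy comparison tables.

#' Two-tailed Wilcoxon signed-rank test
#'
#' Zero differences are dropped; tied absolute differences receive midranks.
#' For `n <= 25` retained pairs the null distribution of the positive-rank
#' sum is computed exactly (over all sign patterns, tie-aware); above that a
#' normal approximation with tie correction and continuity correction is
#' used. Two-sided p doubles the smaller tail (capped at 1).
#'
#' @param x paired differences, or first sample when `y` is given.
#' @param y optional second sample (`x - y` is tested).
#' @return list with `statistic` (positive-rank sum W+), `p_value`, `n_used`
#'   and `method`. All differences zero gives the degenerate `p = 1`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL) {
  d <- if (is.null(y)) x else x - y
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(list(statistic = NA_real_, p_value = 1, n_used = 0L,
                method = "degenerate"))
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  if (n <= 25) {
    # exact null distribution of W+ via dynamic programming on doubled ranks
    # (midranks are half-integers, so 2*r is integral)
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    cnt <- numeric(total + 1)
    cnt[1] <- 1
    for (ri in r2) {
      shifted <- c(rep(0, ri), cnt[seq_len(total + 1 - ri)])
      cnt <- cnt + shifted
    }
    cnt <- cnt / 2^n
    w2 <- as.integer(round(2 * w_pos))
    p_le <- sum(cnt[seq_len(w2 + 1)])
    p_ge <- sum(cnt[(w2 + 1):(total + 1)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w_pos - mu - 0.5 * sign(w_pos - mu)) / sqrt(sig2)
    p <- min(1, 2 * (1 - stats::pnorm(abs(z))))
    method <- "normal_approx"
  }
  list(statistic = w_pos, p_value = p, n_used = n, method = method)
}

#' Holm step-down adjustment
#'
#' Sort ascending; `adjusted_(i) = max_{j <= i} (m - j + 1) * p_(j)`, capped
#' at 1, returned in the input order. Dominates unadjusted p values and is
#' monotone in the Holm ordering.
#'
#' @param p_values vector of p values in `[0, 1]`.
#' @return adjusted p values, same order as the input.
#' @export
holm_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop_param("p values must lie in [0, 1]")
  m <- length(p_values)
  if (m == 0) return(numeric(0))
  o <- order(p_values)
  adj <- pmin(1, cummax((m - seq_len(m) + 1) * p_values[o]))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Bootstrap standard error of the mean
#'
#' SD of the means of `n_boot` seeded resamples (with replacement).
#'
#' @param x numeric vector (here: per-group accuracies), length >= 2.
#' @param n_boot number of resamples.
#' @param seed integer seed.
#' @return SEM estimate, or `NA` for a single observation.
#' @export
bootstrap_sem <- function(x, n_boot = 1000L, seed = 1L) {
  n <- length(x)
  if (n < 2) return(NA_real_)
  with_seed(seed, {
    means <- vapply(seq_len(n_boot),
                    function(i) mean(x[sample.int(n, n, replace = TRUE)]),
                    numeric(1))
    sd(means)
  })
}

#' Pointwise ERP comparison at one channel
#'
#' Grand average = mean over participants of per-participant condition means;
#' per timepoint, a two-tailed Wilcoxon signed-rank test across participants
#' on the paired condition means, masked at `alpha` (unadjusted, as is
#' conventional for ERP shading).
#'
#' @param epochs_list list of conditioned [epoch_set()]s, one per
#'   participant, with `"correct"`/`"incorrect"` labels.
#' @param channel channel label (default FCz).
#' @param alpha significance level for the mask.
#' @return object of class `erp_comparison`: `times_ms`, `mean_correct`,
#'   `mean_incorrect`, `pointwise_p`, `significance_mask`, `n_participants`.
#' @export
erp_compare <- function(epochs_list, channel = "FCz", alpha = 0.05) {
  per_part <- lapply(epochs_list, function(ep) {
    ci <- match(channel, ep$channel_names)
    if (is.na(ci)) stop_param("channel %s not present", channel)
    ok_c <- ep$labels == "correct"; ok_i <- ep$labels == "incorrect"
    if (!any(ok_c) || !any(ok_i)) return(NULL) # excluded pairwise
    list(correct = apply(ep$data[ok_c, ci, , drop = FALSE], 3, mean),
         incorrect = apply(ep$data[ok_i, ci, , drop = FALSE], 3, mean))
  })
  dropped <- vapply(per_part, is.null, logical(1))
  if (any(dropped))
    message(sprintf("%d participant(s) missing a condition; excluded", sum(dropped)))
  per_part <- per_part[!dropped]
  if (!length(per_part)) stop_param("no participant has both conditions")
  mc <- do.call(rbind, lapply(per_part, `[[`, "correct"))
  mi <- do.call(rbind, lapply(per_part, `[[`, "incorrect"))
  nt <- ncol(mc)
  p <- vapply(seq_len(nt), function(j)
    wilcoxon_signed_rank(mc[, j], mi[, j])$p_value, numeric(1))
  structure(list(channel = channel,
                 times_ms = epoch_times_ms(epochs_list[[which(!dropped)[1]]]),
                 mean_correct = colMeans(mc), mean_incorrect = colMeans(mi),
                 pointwise_p = p, significance_mask = p < alpha,
                 alpha = alpha, n_participants = nrow(mc)),
            class = "erp_comparison")
}

#' Scalp snapshot of condition differences at chosen latencies
#'
#' Per channel, the across-participant Wilcoxon signed-rank p value of the
#' correct-vs-incorrect condition means at the sample nearest each requested
#' latency.
#'
#' @param epochs_list list of conditioned [epoch_set()]s.
#' @param latencies_ms latencies relative to the response (default -300 and
#'   -80 ms).
#' @return data frame with `channel`, `latency_ms`, `p_value`,
#'   `mean_difference`.
#' @export
scalp_snapshot <- function(epochs_list, latencies_ms = c(-300, -80)) {
  times <- epoch_times_ms(epochs_list[[1]])
  chans <- epochs_list[[1]]$channel_names
  out <- list()
  for (lat in latencies_ms) {
    j <- which.min(abs(times - lat))
    for (ci in seq_along(chans)) {
      vals <- t(vapply(epochs_list, function(ep) {
        ok_c <- ep$labels == "correct"; ok_i <- ep$labels == "incorrect"
        if (!any(ok_c) || !any(ok_i)) return(c(NA_real_, NA_real_))
        c(mean(ep$data[ok_c, ci, j]), mean(ep$data[ok_i, ci, j]))
      }, numeric(2)))
      vals <- vals[stats::complete.cases(vals), , drop = FALSE]
      wt <- wilcoxon_signed_rank(vals[, 1], vals[, 2])
      out[[length(out) + 1]] <- data.frame(
        channel = chans[ci], latency_ms = lat, p_value = wt$p_value,
        mean_difference = mean(vals[, 1] - vals[, 2]))
    }
  }
  do.call(rbind, out)
}

#' Matched-pairs rank-biserial correlation
#'
#' Effect size for the signed-rank test: `(W+ - W-) / (W+ + W-)`.
#'
#' @param x,y paired samples (or `x` = differences with `y = NULL`).
#' @return effect size in `[-1, 1]`.
#' @export
rank_biserial <- function(x, y = NULL) {
  d <- if (is.null(y)) x else x - y
  d <- d[!is.na(d) & d != 0]
  if (!length(d)) return(NA_real_)
  r <- rank(abs(d))
  (sum(r[d > 0]) - sum(r[d < 0])) / sum(r)
}

#' Pairwise strategy comparisons with Holm adjustment
#'
#' For every pair of strategies and every group size, a two-tailed Wilcoxon
#' signed-rank test across the per-group accuracies (paired by group), with
#' Holm step-down adjustment applied within each strategy pair across sizes.
#'
#' @param accuracy_tables named list of outputs of [strategy_accuracy()] (the
#'   `group_accuracies` attribute is used), one per strategy.
#' @param sizes group sizes to compare (need >= 2 groups, so sizes 2..9 for
#'   ten participants).
#' @return data frame: `size`, `strategy_a`, `strategy_b`, `statistic`,
#'   `p_value`, `p_holm`, `effect_size`, `n_pairs`.
#' @export
compare_strategies <- function(accuracy_tables, sizes = 2:9) {
  nm <- names(accuracy_tables)
  rows <- list()
  for (a in seq_along(nm)) for (b in seq_along(nm)) {
    if (a >= b) next
    pvals <- c(); recs <- list()
    for (m in sizes) {
      ga <- attr(accuracy_tables[[a]], "group_accuracies")[[as.character(m)]]
      gb <- attr(accuracy_tables[[b]], "group_accuracies")[[as.character(m)]]
      wt <- wilcoxon_signed_rank(ga, gb)
      pvals <- c(pvals, wt$p_value)
      recs[[length(recs) + 1]] <- data.frame(
        size = m, strategy_a = nm[a], strategy_b = nm[b],
        statistic = wt$statistic, p_value = wt$p_value, p_holm = NA_real_,
        effect_size = rank_biserial(ga, gb), n_pairs = wt$n_used)
    }
    adj <- holm_adjust(pvals)
    for (i in seq_along(recs)) recs[[i]]$p_holm <- adj[i]
    rows <- c(rows, recs)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
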