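# Anytime group decisions: a tick grid every 100 ms from the first response;
# members who responded are weighted by the pair's no-reported-confidence
# estimator, members whose confidence report has arrived are re-weighted by
# the with-reported-confidence estimator, and the group decision is the
# confidence-weighted majority at every tick.

#' The three anytime strategy pairs
#'
#' Each pair morphs from a no-reported-confidence system to the same system
#' with reported confidence: (1) the two cBCIs (`nf+rt` to `nf+rt+conf`),
#' (2) the behavioural systems (`rt` to `rt+conf`), and (3) standard majority
#' (static weight equal to the mean training accuracy of all participants) to
#' reported-confidence-weighted majority.
#'
#' @return list of three pairs, each with `name`, `pre`, `post` and
#'   `static_pre` (`TRUE` only for the majority pair, whose pre-report weight
#'   is a constant rather than an estimator output).
#' @export
anytime_pairs <- function() {
  list(
    cbci = list(name = "cbci", pre = "nf+rt", post = "nf+rt+conf",
                static_pre = FALSE),
    rt = list(name = "rt", pre = "rt", post = "rt+conf", static_pre = FALSE),
    majority = list(name = "majority", pre = "static", post = "repconf",
                    static_pre = TRUE))
}

#' Anytime decision trace for one trial and one group
#'
#' Tick 0 sits at the first response among the group's members; ticks advance
#' every `tick_s` seconds until every member's decision and confidence report
#' have arrived (or `horizon_s`, if sooner for members who never respond).
#' At each tick a member contributes weight `w_pre` once responded and
#' `w_post` once their confidence report has also arrived; the group decision
#' is the weighted majority, ties broken by a seeded coin.
#'
#' @param decisions member decisions (`+1`/`-1`, `NA` = never responds).
#' @param resp_times absolute member response times (s), `NA` allowed.
#' @param conf_times absolute confidence-report times (s), `NA` allowed.
#' @param w_pre,w_post member weights before/after their report arrives.
#' @param tick_s tick spacing (s), default 0.1.
#' @param horizon_s latest event time considered when some member never
#'   responds (default: first response + 4.5 s, the response deadline plus
#'   the reporting window).
#' @param tie_seed seed for tie-break coins.
#' @return object of class `anytime_trace`: data frame `ticks` (`tick`,
#'   `time_s`, `n_responders`, `n_reporters`, `decision`) plus
#'   `final_decision`.
#' @export
anytime_trace <- function(decisions, resp_times, conf_times, w_pre, w_post,
                          tick_s = 0.1, horizon_s = NULL, tie_seed = 0L) {
  m <- length(decisions)
  stopifnot(length(resp_times) == m, length(conf_times) == m,
            length(w_pre) == m, length(w_post) == m)
  if (all(is.na(resp_times) | is.na(decisions))) {
    return(structure(list(ticks = data.frame(tick = integer(0),
                                             time_s = numeric(0),
                                             n_responders = integer(0),
                                             n_reporters = integer(0),
                                             decision = integer(0)),
                          final_decision = NA_integer_),
                     class = "anytime_trace"))
  }
  t0 <- min(resp_times, na.rm = TRUE)
  horizon_s <- horizon_s %||% (t0 + 4.5)
  t_end <- max(c(resp_times, conf_times, t0), na.rm = TRUE)
  if (anyNA(resp_times)) t_end <- max(t_end, horizon_s)
  n_ticks <- ceiling((t_end - t0) / tick_s - 1e-9) + 1L
  ticks <- lapply(seq_len(n_ticks) - 1L, function(k) {
    tm <- t0 + k * tick_s
    responded <- !is.na(resp_times) & resp_times <= tm + 1e-12 & !is.na(decisions)
    reported <- responded & !is.na(conf_times) & conf_times <= tm + 1e-12
    w <- ifelse(reported, w_post, ifelse(responded, w_pre, 0))
    d <- ifelse(responded, decisions, 0L)
    # one coin per trace: an exact tie resolves the same way at every tick
    # (and identically in the non-anytime path given the same seed)
    dec <- weighted_decision(d, w, tie_seed = tie_seed)
    data.frame(tick = k, time_s = tm, n_responders = sum(responded),
               n_reporters = sum(reported), decision = dec)
  })
  ticks <- do.call(rbind, ticks)
  structure(list(ticks = ticks,
                 final_decision = ticks$decision[nrow(ticks)]),
            class = "anytime_trace")
}

# Resolve the (pre, post) weight matrices of a pair against a pipeline run.
pair_weights <- function(run, pair) {
  if (pair$static_pre) {
    static <- mean(run$training_accuracies)
    w_pre <- matrix(static, nrow(run$decisions), ncol(run$decisions))
    w_post <- run$reported_conf / 100
  } else {
    w_pre <- run$weights[[pair$pre]]
    w_post <- run$weights[[pair$post]]
  }
  list(pre = w_pre, post = w_post)
}

#' Accuracy-versus-time curves for an anytime pair
#'
#' For every group of each requested size, evaluates the anytime decision on
#' a shared relative tick grid (tick 0 at the group's first response in each
#' trial) and averages correctness over groups and trials; also returns the
#' mean responder and reporter counts per tick.
#'
#' @param run a pipeline run from [run_pipeline()].
#' @param pair one element of [anytime_pairs()].
#' @param group_sizes sizes to evaluate.
#' @param n_ticks ticks in the grid (default 46: 4.5 s at 100 ms).
#' @param tick_s tick spacing (s).
#' @param seed seed for tie-break coins.
#' @return data frame: `size`, `tick`, `time_s`, `accuracy`,
#'   `mean_responders`, `mean_reporters`, `sem` (bootstrap over groups).
#' @export
accuracy_vs_time <- function(run, pair, group_sizes = 2:5, n_ticks = 46L,
                             tick_s = 0.1, seed = 1L) {
  w <- pair_weights(run, pair)
  D <- run$decisions; D0 <- D; D0[is.na(D0)] <- 0L
  R <- run$resp_times; C <- run$conf_times
  truth <- run$truth
  n_trial <- nrow(D)
  out <- list()
  for (m in group_sizes) {
    groups <- enumerate_groups(ncol(D), m)
    acc <- matrix(0, length(groups), n_ticks)
    nresp <- matrix(0, length(groups), n_ticks)
    nrep <- matrix(0, length(groups), n_ticks)
    for (gi in seq_along(groups)) {
      g <- groups[[gi]]
      Rg <- R[, g, drop = FALSE]; Cg <- C[, g, drop = FALSE]
      Dg <- D0[, g, drop = FALSE]
      Wpre <- w$pre[, g, drop = FALSE]; Wpost <- w$post[, g, drop = FALSE]
      Wpre[is.na(Wpre) | Dg == 0] <- 0
      Wpost[is.na(Wpost) | Dg == 0] <- 0
      t0 <- suppressWarnings(apply(Rg, 1, min, na.rm = TRUE)) # per-trial first response
      no_resp <- !is.finite(t0)
      Rrel <- Rg - t0; Crel <- Cg - t0
      for (k in seq_len(n_ticks) - 1L) {
        tm <- k * tick_s + 1e-12
        responded <- !is.na(Rrel) & Rrel <= tm
        reported <- responded & !is.na(Crel) & Crel <= tm
        W <- Wpre * (responded & !reported) + Wpost * reported
        s <- rowSums(W * Dg * responded)
        dec <- sign(s)
        ties <- which(dec == 0 & rowSums(responded & Dg != 0) > 0)
        for (i in ties)
          dec[i] <- tie_coin(derive_seed(seed, i * 2003L + gi * 7L + k))
        dec[no_resp] <- 0L
        acc[gi, k + 1] <- mean(dec == truth)
        nresp[gi, k + 1] <- mean(rowSums(responded))
        nrep[gi, k + 1] <- mean(rowSums(reported))
      }
    }
    sems <- vapply(seq_len(n_ticks), function(k)
      bootstrap_sem(acc[, k], n_boot = 200L, seed = derive_seed(seed, k + m * 100L)),
      numeric(1))
    out[[as.character(m)]] <- data.frame(
      size = m, tick = seq_len(n_ticks) - 1L,
      time_s = (seq_len(n_ticks) - 1L) * tick_s,
      accuracy = colMeans(acc), mean_responders = colMeans(nresp),
      mean_reporters = colMeans(nrep), sem = sems)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
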