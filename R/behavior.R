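# Trial-level and subject-level behavioural measures: SSRT by the
# integration method, stop-task descriptives, go-RT slowing across runs,
# and conditionalized suppression-induced forgetting.

#' Estimate SSRT with the integration method (go-omission replacement)
#'
#' Pools all go trials (correct and incorrect), replacing omitted go RTs by
#' the maximum observed go RT; takes the n-th fastest go RT where
#' n = round(N_go x p(respond|stop)), rounded half away from zero and
#' clamped to \[1, N_go\]; and subtracts the mean SSD over all stop trials.
#' Also returns stop-task descriptives and the independent-race assumption
#' check (mean failed-stop RT < mean correct go RT).
#'
#' @param trials Trial table for a single subject (see
#'   [simulate_stop_signal()] for the column layout).
#' @return A list of class `stop_summary` with `ssrt_ms`, `p_respond_stop`,
#'   `p_go_omission`, `p_go_choice_error`, `mean_ssd_ms`,
#'   `mean_correct_go_rt_ms`, `mean_failed_stop_rt_ms`,
#'   `race_assumption_ok`.
#' @export
estimate_ssrt_integration <- function(trials) {
  if (length(unique(trials$subject)) > 1) {
    stop("estimate_ssrt_integration expects a single subject; ",
         "see stop_summary_by_subject()")
  }
  go <- trials[trials$trial_type == "go", ]
  st <- trials[trials$trial_type == "stop", ]
  if (nrow(st) == 0) stop("no stop trials")
  if (nrow(go) == 0) stop("no go trials")
  responded <- !is.na(st$rt_ms)
  p_respond <- mean(responded)
  if (p_respond == 0) stop("SSRT undefined at zero respond rate")
  go_rt <- go$rt_ms
  omitted <- is.na(go_rt)
  if (all(omitted)) stop("no observed go RTs")
  go_rt[omitted] <- max(go_rt, na.rm = TRUE)
  n_go <- length(go_rt)
  n <- min(max(round_half_away(n_go * p_respond), 1), n_go)
  nth_rt <- sort(go_rt)[n]
  mean_ssd <- mean(st$ssd_ms)
  correct_go <- !is.na(go$rt_ms) & go$correct
  out <- list(
    ssrt_ms = nth_rt - mean_ssd,
    p_respond_stop = p_respond,
    p_go_omission = mean(omitted),
    p_go_choice_error = mean(!is.na(go$rt_ms) & !go$correct),
    mean_ssd_ms = mean_ssd,
    mean_correct_go_rt_ms = mean(go$rt_ms[correct_go]),
    mean_failed_stop_rt_ms = if (any(responded)) {
      mean(st$rt_ms[responded])
    } else NA_real_)
  out$race_assumption_ok <-
    isTRUE(out$mean_failed_stop_rt_ms < out$mean_correct_go_rt_ms)
  class(out) <- "stop_summary"
  out
}

#' Per-subject stop-task summaries
#'
#' @param trials Multi-subject trial table.
#' @return A data.frame with one row per subject and the `stop_summary`
#'   fields as columns.
#' @export
stop_summary_by_subject <- function(trials) {
  subs <- sort(unique(trials$subject))
  do.call(rbind, lapply(subs, function(s) {
    sm <- estimate_ssrt_integration(trials[trials$subject == s, ])
    data.frame(subject = s, as.data.frame(unclass(sm)))
  }))
}

#' Go-RT slowing across runs
#'
#' Per-subject least-squares slope of correct go RT on run index; the group
#' slope is the mean of subject slopes, tested against zero with a
#' two-sided one-sample t-test. (A pooled mixed-model coefficient is a
#' near-equivalent alternative; the per-subject mean is used here.)
#'
#' @param trials Multi-subject trial table.
#' @return A list with `slope_ms_per_run`, `t`, `df`, `p`, and the
#'   per-subject slopes.
#' @export
go_rt_run_slope <- function(trials) {
  subs <- sort(unique(trials$subject))
  slopes <- vapply(subs, function(s) {
    d <- trials[trials$subject == s & trials$trial_type == "go" &
                  !is.na(trials$rt_ms) & trials$correct, ]
    if (length(unique(d$run)) < 2) {
      stop("subject ", s, ": at least two runs with correct go trials ",
           "are required")
    }
    unname(coef(lm.fit(cbind(1, d$run), d$rt_ms))[2])
  }, numeric(1))
  if (length(slopes) >= 2 && sd(slopes) > 0) {
    tt <- t.test(slopes, mu = 0)
    list(slope_ms_per_run = mean(slopes), t = unname(tt$statistic),
         df = unname(tt$parameter), p = tt$p.value, per_subject = slopes)
  } else {
    list(slope_ms_per_run = mean(slopes), t = NA_real_,
         df = length(slopes) - 1, p = NA_real_, per_subject = slopes)
  }
}

#' Conditionalized suppression-induced forgetting score
#'
#' Excludes filler pairs and pairs not learned at the criterion test; per
#' condition, computes the recall proportion separately for the same-probe
#' and independent-probe tests and averages the two; SIF is Baseline minus
#' NoThink recall.
#'
#' @param recall Recall table for a single subject (columns `pair_id`,
#'   `condition`, `learned`, `sp_correct`, `ip_correct`).
#' @return A list of class `sif_score` with `recall_baseline`,
#'   `recall_nothink`, `recall_think`, `sif`.
#' @export
score_sif <- function(recall) {
  if (!is.null(recall$subject) && length(unique(recall$subject)) > 1) {
    stop("score_sif expects a single subject; see sif_by_subject()")
  }
  d <- recall[recall$condition != "filler" & recall$learned, ]
  prop <- function(cond) {
    dd <- d[d$condition == cond, ]
    if (nrow(dd) == 0) stop("no learned pairs in condition ", cond)
    (mean(dd$sp_correct) + mean(dd$ip_correct)) / 2
  }
  out <- list(recall_baseline = prop("Baseline"),
              recall_nothink = prop("NoThink"),
              recall_think = prop("Think"))
  out$sif <- out$recall_baseline - out$recall_nothink
  class(out) <- "sif_score"
  out
}

#' Per-subject SIF scores
#'
#' @param recall Multi-subject recall table.
#' @return A data.frame with one row per subject.
#' @export
sif_by_subject <- function(recall) {
  subs <- sort(unique(recall$subject))
  do.call(rbind, lapply(subs, function(s) {
    sc <- score_sif(recall[recall$subject == s, ])
    data.frame(subject = s, as.data.frame(unclass(sc)))
  }))
}

#' One-sample group test with standardized effect size
#'
#' Student t-test of per-subject scalars against `mu0`. Cohen's d is
#' computed as t / sqrt(n). The one-tailed p-value is the upper-tail
#' probability (hypothesised direction: values > `mu0`).
#'
#' @param values Per-subject scalars (n >= 2).
#' @param tail "one" (upper tail) or "two".
#' @param mu0 Null value (default 0).
#' @return A list with `t`, `df`, `p`, `d`, `mean`.
#' @export
group_one_sample_test <- function(values, tail = c("two", "one"), mu0 = 0) {
  tail <- match.arg(tail)
  n <- length(values)
  if (n < 2) stop("need at least 2 values")
  s <- sd(values)
  t <- if (s == 0) {
    if (mean(values) == mu0) 0 else Inf * sign(mean(values) - mu0)
  } else {
    (mean(values) - mu0) / (s / sqrt(n))
  }
  df <- n - 1
  p <- if (tail == "one") 1 - pt(t, df) else 2 * (1 - pt(abs(t), df))
  list(t = t, df = df, p = p, d = t / sqrt(n), mean = mean(values))
}
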