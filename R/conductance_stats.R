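#' Analysis configuration
#'
#' Tunable parameters of the channel analysis. Defaults encode the
#' published analysis conventions (<10 ms transition rule, 30-s
#' pre-blocker mean-conductance window, 4-s charge window) and this
#' package's operational choices for quantities the convention leaves
#' open (stability dwell, event threshold, hysteresis, bin width).
#'
#' @param max_transition_duration_ms maximal duration of a conductance
#'   transition counted by G_max, ms.
#' @param gmean_window_s length of the pre-blocker window used by G_mean, s.
#' @param q_interval_s length of the charge-integration window, s.
#' @param min_stable_dwell_ms minimal dwell for a level to count as a
#'   stable state, ms (about 30x the 500-Hz filter rise time).
#' @param event_threshold_sigmas separation from baseline, in baseline
#'   standard deviations, below which a fitted component is merged into
#'   the baseline ("events out of the noise range").
#' @param hysteresis_fraction idealization hysteresis, as a fraction of
#'   the inter-level gap.
#' @param bin_width_pA amplitude-histogram bin width, pA.
#' @param gmean_include_closed if `TRUE`, G_mean averages all samples in
#'   the window rather than activity (non-baseline) samples only.
#' @return object of class `analysis_config`.
#' @export
analysis_config <- function(max_transition_duration_ms = 10,
                            gmean_window_s = 30,
                            q_interval_s = 4,
                            min_stable_dwell_ms = 20,
                            event_threshold_sigmas = 3,
                            hysteresis_fraction = 0.25,
                            bin_width_pA = 0.2,
                            gmean_include_closed = FALSE) {
  vals <- c(max_transition_duration_ms, gmean_window_s, q_interval_s,
            min_stable_dwell_ms, event_threshold_sigmas,
            hysteresis_fraction, bin_width_pA)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all analysis_config parameters must be strictly positive",
         call. = FALSE)
  structure(list(max_transition_duration_ms = max_transition_duration_ms,
                 gmean_window_s = gmean_window_s,
                 q_interval_s = q_interval_s,
                 min_stable_dwell_ms = min_stable_dwell_ms,
                 event_threshold_sigmas = event_threshold_sigmas,
                 hysteresis_fraction = hysteresis_fraction,
                 bin_width_pA = bin_width_pA,
                 gmean_include_closed = isTRUE(gmean_include_closed)),
            class = "analysis_config")
}

#' Inclusion rule: does a trace carry events out of the noise range?
#'
#' A trace is included in the mean-conductance analysis only if at least
#' one fitted amplitude component survives the baseline merge rule
#' (separation > `event_threshold_sigmas` baseline sigmas) and the
#' channel dwells on a non-baseline level for at least
#' `min_stable_dwell_ms` at least once. Traces failing this rule are
#' reported as showing no current activity, which is distinct from a
#' measured conductance of zero.
#'
#' @param trace a `ptp_trace`.
#' @param fit a [fit_mixture()] result for the trace.
#' @param config an [analysis_config()].
#' @return logical flag.
#' @export
has_events <- function(trace, fit, config = analysis_config()) {
  levels <- extract_levels(fit, trace$protocol, config$event_threshold_sigmas)
  if (nrow(levels$levels) < 2L) return(FALSE)
  ideal <- idealize(trace, levels, config)
  seg <- ideal$segments
  any(seg$level > 0L & seg$dwell_ms >= config$min_stable_dwell_ms)
}

#' Maximal transition conductance G_max
#'
#' The largest conductance jump between two stable states completed in
#' less than `max_transition_duration_ms` (default 10 ms). Events are the
#' output of [detect_transitions()], whose segments already satisfy the
#' stable-dwell rule. Returns `NA` ("no current activity") when no event
#' qualifies; this is deliberately distinct from a G_max of 0.
#'
#' @param events data.frame from [detect_transitions()].
#' @param config an [analysis_config()].
#' @return G_max in pS, or `NA_real_` if no qualifying event exists.
#' @export
compute_gmax <- function(events, config = analysis_config()) {
  if (is.null(events) || nrow(events) == 0L) return(NA_real_)
  ok <- events$duration_ms < config$max_transition_duration_ms
  if (!any(ok)) return(NA_real_)
  max(abs(events$delta_g_pS[ok]))
}

#' Mean open conductance G_mean
#'
#' Offset-corrected average conductance during channel activity in the
#' `gmean_window_s` seconds before blocker administration: the mean of
#' baseline-corrected current over samples idealized to non-baseline
#' levels within `[blocker_time - 30 s, blocker_time)`, divided by V_h.
#' Closed dwells are excluded from the average unless
#' `config$gmean_include_closed` is set.
#'
#' @param trace a `ptp_trace`.
#' @param ideal a [idealize()] result.
#' @param levels the [extract_levels()] result used for `ideal`.
#' @param blocker_time blocker administration time, s. Windows reaching
#'   before the trace start are truncated (and flagged in the result
#'   attributes).
#' @param config an [analysis_config()].
#' @return G_mean in pS (`NA_real_` if the window contains no activity),
#'   with attribute `window` = `c(start_s, end_s)` and `truncated` flag.
#' @export
compute_gmean <- function(trace, ideal, levels, blocker_time,
                          config = analysis_config()) {
  fs <- trace$protocol$sampling_rate_hz
  vh <- trace$protocol$holding_potential_mV
  w0 <- blocker_time - config$gmean_window_s
  truncated <- w0 < 0
  w0 <- max(0, w0)
  t <- trace_times(trace)
  corrected <- correct_baseline(trace, ideal, levels)
  lv <- idealized_levels(ideal)
  in_win <- t >= w0 & t < blocker_time
  use <- if (config$gmean_include_closed) in_win else in_win & lv > 0L
  out <- if (!any(use)) NA_real_ else mean(corrected[use]) / vh * 1000
  attr(out, "window") <- c(w0, blocker_time)
  attr(out, "truncated") <- truncated
  out
}

#' Charge transfer at maximal activity Q_4s
#'
#' The net charge passing through the channel in the contiguous
#' `q_interval_s`-second window (default 4 s) of maximal activity:
#' the maximum over all window positions of the trapezoidal integral of
#' the baseline-corrected current. pA integrated over seconds gives pC.
#'
#' @inheritParams compute_gmean
#' @return Q_4s in pC with attribute `window` = `c(start_s, end_s)` of the
#'   maximizing window.
#' @export
compute_q4s <- function(trace, ideal, levels, config = analysis_config()) {
  fs <- trace$protocol$sampling_rate_hz
  dt <- 1 / fs
  w <- round(config$q_interval_s * fs) + 1L    # samples spanning 4 s
  x <- correct_baseline(trace, ideal, levels)
  n <- length(x)
  if (n < w)
    stop("trace shorter than the ", config$q_interval_s,
         "-s charge window", call. = FALSE)
  cs <- c(0, cumsum(x))
  starts <- seq_len(n - w + 1L)
  sums <- cs[starts + w] - cs[starts]
  integrals <- dt * (sums - (x[starts] + x[starts + w - 1L]) / 2)
  best <- which.max(integrals)
  out <- integrals[best]
  attr(out, "window") <- c(best - 1L, best - 1L + (w - 1L)) / fs
  out
}

#' Full channel analysis of one recording
#'
#' Runs the complete pipeline on one trace: amplitude-mixture fit, level
#' extraction, idealization, transition detection, inclusion rule, and
#' the per-experiment statistics G_max, G_mean and Q_4s. When
#' `blocker_time` is given (or recorded in the trace's interventions),
#' G_max is computed from pre-blocker events and G_mean over the 30-s
#' pre-blocker window; post-blocker G_max is also reported for paired
#' blocker-effect comparisons (absent statistics are `NA`).
#'
#' @param trace a `ptp_trace`.
#' @param config an [analysis_config()].
#' @param blocker_time blocker administration time, s; default the first
#'   recorded intervention, or the trace end when there is none (G_mean
#'   then covers the final 30 s and no post window exists).
#' @param blocker_settle_s settling period after blocker addition excluded
#'   from the post-blocker G_max, s. Pore closure rapidly follows blocker
#'   addition, and the closing transitions of that transient would
#'   otherwise register as large post-blocker conductance jumps.
#' @return object of class `conductance_stats`: list with `included`,
#'   `gmax_pS`, `gmean_pS`, `q4s_pC`, `gmax_post_pS`, `blocker_time_s`,
#'   `gmean_window_s`, `q_window_s`, `note`, plus the intermediate `fit`,
#'   `levels`, `ideal`, `events`.
#' @export
analyze_trace <- function(trace, config = analysis_config(),
                          blocker_time = NULL, blocker_settle_s = 1) {
  if (is.null(blocker_time)) {
    blocker_time <- if (length(trace$interventions))
      trace$interventions[[1]]$time_s else trace$protocol$duration_s
  }
  fit <- fit_mixture(trace$current_pA, bin_width_pA = config$bin_width_pA)
  levels <- extract_levels(fit, trace$protocol, config$event_threshold_sigmas)
  ideal <- idealize(trace, levels, config)
  events <- detect_transitions(ideal, trace, levels)
  included <- nrow(levels$levels) >= 2L &&
    any(ideal$segments$level > 0L &
        ideal$segments$dwell_ms >= config$min_stable_dwell_ms)
  res <- list(included = included, gmax_pS = NA_real_, gmean_pS = NA_real_,
              q4s_pC = NA_real_, gmax_post_pS = NA_real_,
              blocker_time_s = blocker_time,
              gmean_window_s = c(NA_real_, NA_real_),
              q_window_s = c(NA_real_, NA_real_),
              note = "no current activity",
              fit = fit, levels = levels, ideal = ideal, events = events)
  if (included) {
    pre <- events[events$time_s < blocker_time, , drop = FALSE]
    post <- events[events$time_s >= blocker_time + blocker_settle_s, ,
                   drop = FALSE]
    res$gmax_pS <- compute_gmax(pre, config)
    res$gmax_post_pS <- if (blocker_time < trace$protocol$duration_s)
      compute_gmax(post, config) else NA_real_
    gmean <- compute_gmean(trace, ideal, levels, blocker_time, config)
    res$gmean_pS <- as.numeric(gmean)
    res$gmean_window_s <- attr(gmean, "window")
    q <- compute_q4s(trace, ideal, levels, config)
    res$q4s_pC <- as.numeric(q)
    res$q_window_s <- attr(q, "window")
    res$note <- ""
  }
  class(res) <- "conductance_stats"
  res
}

#' @export
print.conductance_stats <- function(x, ...) {
  cat("<conductance_stats>\n")
  if (!x$included) {
    cat("  excluded: ", x$note, "\n", sep = "")
    return(invisible(x))
  }
  cat("  G_max  ", round(x$gmax_pS, 1), " pS (pre-blocker)\n", sep = "")
  cat("  G_mean ", round(x$gmean_pS, 1), " pS over [",
      round(x$gmean_window_s[1], 1), ", ", round(x$gmean_window_s[2], 1),
      ") s\n", sep = "")
  cat("  Q_4s   ", round(x$q4s_pC, 1), " pC over [",
      round(x$q_window_s[1], 1), ", ", round(x$q_window_s[2], 1), "] s\n",
      sep = "")
  if (!is.na(x$gmax_post_pS))
    cat("  G_max (post-blocker) ", round(x$gmax_post_pS, 1), " pS\n", sep = "")
  invisible(x)
}

new_test_result <- function(ht, paired, n) {
  structure(list(statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = unname(ht$p.value),
                 paired = paired, n = n,
                 method = ht$method),
            class = "ptp_test_result")
}

#' @export
print.ptp_test_result <- function(x, ...) {
  cat("<ptp_test_result> ", x$method, "\n  t = ", round(x$statistic, 3),
      ", df = ", round(x$df, 2), ", p = ", signif(x$p_value, 3),
      ", n = ", paste(x$n, collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' Paired blocker-effect test
#'
#' Two-sided paired Student's t-test on per-experiment statistics (e.g.
#' G_max) before and after blocker addition, pairing by experiment.
#'
#' @param pre,post numeric vectors of equal length n >= 2, one value per
#'   experiment.
#' @return object of class `ptp_test_result` with `statistic`, `df`
#'   (n - 1), `p_value`, `paired = TRUE`, `n`.
#' @export
blocker_effect <- function(pre, post) {
  if (length(pre) != length(post))
    stop("pre and post must pair by experiment: lengths ", length(pre),
         " and ", length(post), " differ", call. = FALSE)
  if (length(pre) < 2L)
    stop("need at least 2 paired experiments", call. = FALSE)
  d <- pre - post
  if (stats::sd(d) == 0 && mean(d) == 0) {
    # identical pre/post: t = 0, p = 1 (t.test errors on constant data)
    return(structure(list(statistic = 0, df = length(pre) - 1L,
                          p_value = 1, paired = TRUE, n = length(pre),
                          method = "Paired t-test"),
                     class = "ptp_test_result"))
  }
  ht <- stats::t.test(pre, post, paired = TRUE, alternative = "two.sided")
  new_test_result(ht, paired = TRUE, n = length(pre))
}

#' Two-sample group comparison
#'
#' Two-sided two-sample Student's t-test (pooled variance by default,
#' Welch as an option) between two groups of per-experiment values.
#' Groups with zero variance in both samples and equal means are reported
#' as t = 0, p = 1; zero variance with different means is a degenerate
#' input and raises an error.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param welch use the Welch (unequal-variance) test.
#' @return object of class `ptp_test_result`.
#' @export
group_compare <- function(a, b, welch = FALSE) {
  if (length(a) < 2L || length(b) < 2L)
    stop("need at least 2 observations per group", call. = FALSE)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b))
      return(structure(list(statistic = 0, df = length(a) + length(b) - 2L,
                            p_value = 1, paired = FALSE,
                            n = c(length(a), length(b)),
                            method = "Two Sample t-test"),
                       class = "ptp_test_result"))
    stop("degenerate comparison: both groups have zero variance but ",
         "different means (t statistic is unbounded)", call. = FALSE)
  }
  ht <- stats::t.test(a, b, var.equal = !welch, alternative = "two.sided")
  new_test_result(ht, paired = FALSE, n = c(length(a), length(b)))
}
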