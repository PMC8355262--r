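#' Current amplitude histogram
#'
#' Histogram of current samples in a time window, the basis of the
#' multi-Gaussian level analysis. Bin edges are aligned to multiples of
#' `bin_width_pA` so that every sample falls in exactly one bin and the
#' counts conserve the sample count.
#'
#' @param trace a `ptp_trace`.
#' @param window optional `c(start_s, end_s)` time window (half-open);
#'   default the whole trace.
#' @param bin_width_pA bin width, pA.
#' @return object of class `amplitude_histogram`: list with `bin_edges_pA`,
#'   `counts`, `n`.
#' @export
build_histogram <- function(trace, window = NULL, bin_width_pA = 0.2) {
  stopifnot(bin_width_pA > 0)
  x <- window_samples(trace, window)
  if (length(x) == 0L)
    stop("empty window: no samples between ", window[1], " and ", window[2],
         " s", call. = FALSE)
  lo <- floor(min(x) / bin_width_pA) * bin_width_pA
  hi <- ceiling(max(x) / bin_width_pA) * bin_width_pA
  if (hi <= lo) hi <- lo + bin_width_pA
  edges <- seq(lo, hi, by = bin_width_pA)
  if (edges[length(edges)] < hi) edges <- c(edges, hi)
  # right-open bins, last bin closed so max(x) is counted
  idx <- pmin(findInterval(x, edges), length(edges) - 1L)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  structure(list(bin_edges_pA = edges, counts = counts, n = length(x)),
            class = "amplitude_histogram")
}

window_samples <- function(trace, window = NULL) {
  x <- trace$current_pA
  if (is.null(window)) return(x)
  stopifnot(length(window) == 2L, window[2] > window[1])
  t <- trace_times(trace)
  x[t >= window[1] & t < window[2]]
}

#' Multi-Gaussian fit of the current amplitude distribution
#'
#' Fits Gaussian mixtures with 1..`k_max` components by EM and selects the
#' number of components by BIC. Fitting is done on the raw samples (the
#' histogram is a reporting device); `binned = TRUE` instead fits the
#' samples rounded to the histogram bin width, for comparison with a
#' purely histogram-based analysis. Long traces are decimated
#' deterministically to at most `max_fit_samples` evenly spaced samples,
#' which preserves level occupancies because gating dwells span many
#' samples. The fit is deterministic for a given input.
#'
#' @param samples numeric vector of current samples, pA (at least 200).
#' @param k_max maximum number of mixture components.
#' @param binned fit bin centers instead of raw samples.
#' @param bin_width_pA bin width used when `binned = TRUE`.
#' @param max_fit_samples decimation ceiling for the EM fit.
#' @return object of class `mixture_fit`: list with `components`
#'   (data.frame `weight`, `mean_pA`, `sd_pA`, sorted by mean), `k`,
#'   `log_likelihood`, `bic`, `n`.
#' @export
fit_mixture <- function(samples, k_max = 6, binned = FALSE,
                        bin_width_pA = 0.2, max_fit_samples = 20000) {
  samples <- as.numeric(samples)
  if (length(samples) < 200L)
    stop("need at least 200 samples to fit the amplitude mixture",
         call. = FALSE)
  stopifnot(k_max >= 1)
  x <- samples
  if (binned) x <- round(x / bin_width_pA) * bin_width_pA
  if (length(x) > max_fit_samples)
    x <- x[unique(round(seq(1, length(x), length.out = max_fit_samples)))]
  init <- list(subset = unique(round(seq(1, length(x),
                                         length.out = min(length(x), 1500)))))
  fit <- mclust::Mclust(x, G = seq_len(k_max), modelNames = c("E", "V"),
                        initialization = init, verbose = FALSE)
  if (is.null(fit))
    stop("mixture fitting failed to converge for any k in 1..", k_max,
         " (n = ", length(x), ", range ", paste(round(range(x), 3),
                                                collapse = " to "), " pA)",
         call. = FALSE)
  p <- fit$parameters
  sds <- sqrt(p$variance$sigmasq)
  if (length(sds) == 1L) sds <- rep(sds, fit$G)
  comp <- data.frame(weight = p$pro, mean_pA = as.numeric(p$mean),
                     sd_pA = sds)
  comp <- comp[order(comp$mean_pA), , drop = FALSE]
  rownames(comp) <- NULL
  structure(list(components = comp, k = fit$G,
                 log_likelihood = fit$loglik, bic = fit$bic,
                 n = length(x)),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("<mixture_fit> k = ", x$k, ", logLik = ", round(x$log_likelihood, 1),
      "\n", sep = "")
  print(transform(x$components,
                  weight = round(weight, 3),
                  mean_pA = round(mean_pA, 3),
                  sd_pA = round(sd_pA, 3)))
  invisible(x)
}

#' Conductance levels from a mixture fit
#'
#' Converts fitted amplitude components into discrete conductance levels.
#' The lowest-mean component is the closed baseline; components whose mean
#' lies within `event_threshold_sigmas` baseline standard deviations of
#' the baseline are merged into it (weight-averaged), so noise shoulders
#' are never reported as conductance states. Each surviving component
#' becomes a level with conductance `(mean - baseline) / V_h * 1000` pS
#' (current in pA, V_h in mV).
#'
#' @param fit a [fit_mixture()] result.
#' @param protocol the [recording_protocol()] (supplies V_h).
#' @param event_threshold_sigmas merge threshold in baseline sigmas.
#' @return object of class `conductance_levels`: list with
#'   `baseline_current_pA`, `baseline_sd_pA`, `v_h_mV` and `levels`
#'   (data.frame `level`, `current_pA`, `conductance_pS`; level 0 is the
#'   baseline with conductance 0, conductances strictly increasing).
#' @export
extract_levels <- function(fit, protocol, event_threshold_sigmas = 3) {
  stopifnot(inherits(fit, "mixture_fit"))
  if (protocol$holding_potential_mV == 0)
    stop("V_h must be non-zero to convert current to conductance",
         call. = FALSE)
  comp <- fit$components
  base_sd <- comp$sd_pA[1]
  merge <- abs(comp$mean_pA - comp$mean_pA[1]) <
    event_threshold_sigmas * base_sd
  w <- comp$weight[merge]
  base_mean <- sum(comp$mean_pA[merge] * w) / sum(w)
  base_sd <- sqrt(sum(w * (comp$sd_pA[merge]^2 +
                           (comp$mean_pA[merge] - base_mean)^2)) / sum(w))
  keep <- comp[!merge, , drop = FALSE]
  vh <- protocol$holding_potential_mV
  lev <- data.frame(level = seq_len(nrow(keep) + 1L) - 1L,
                    current_pA = c(base_mean, keep$mean_pA),
                    conductance_pS = c(0, (keep$mean_pA - base_mean) / vh * 1000))
  structure(list(baseline_current_pA = base_mean, baseline_sd_pA = base_sd,
                 v_h_mV = vh, levels = lev),
            class = "conductance_levels")
}

#' Define conductance levels from known level currents
#'
#' Builds a `conductance_levels` object directly from known level
#' currents, bypassing the mixture fit — useful when the levels are known
#' a priori (simulated ground truth, or levels carried over from another
#' recording of the same patch). The lowest current is the baseline.
#'
#' @param currents_pA numeric vector of level currents, pA (the smallest
#'   becomes the baseline).
#' @param protocol a [recording_protocol()] (supplies V_h).
#' @param baseline_sd_pA nominal baseline noise, pA.
#' @return a `conductance_levels` object.
#' @export
define_levels <- function(currents_pA, protocol, baseline_sd_pA = 0) {
  mu <- sort(as.numeric(currents_pA))
  vh <- protocol$holding_potential_mV
  if (vh == 0) stop("V_h must be non-zero", call. = FALSE)
  structure(list(baseline_current_pA = mu[1], baseline_sd_pA = baseline_sd_pA,
                 v_h_mV = vh,
                 levels = data.frame(level = seq_along(mu) - 1L,
                                     current_pA = mu,
                                     conductance_pS = (mu - mu[1]) / vh * 1000)),
            class = "conductance_levels")
}

#' @export
print.conductance_levels <- function(x, ...) {
  cat("<conductance_levels> baseline ", round(x$baseline_current_pA, 3),
      " pA (sd ", round(x$baseline_sd_pA, 3), "), V_h ", x$v_h_mV, " mV\n",
      sep = "")
  print(transform(x$levels, current_pA = round(current_pA, 3),
                  conductance_pS = round(conductance_pS, 1)))
  invisible(x)
}

#' Idealize a trace onto discrete conductance levels
#'
#' Assigns every filtered sample to the nearest level current with
#' hysteresis (a level switch requires crossing the midpoint between the
#' two levels by more than `hysteresis_fraction` of their gap), then
#' merges dwells shorter than `min_stable_dwell_ms` into the flanking
#' level whose current is nearer, so that only stable states remain.
#' Segments tile the trace exactly.
#'
#' @param trace a `ptp_trace`.
#' @param levels a [extract_levels()] result.
#' @param config an [analysis_config()].
#' @return object of class `ptp_idealization`: list with `segments`
#'   (data.frame `start` and `end` sample indices, half-open 1-based,
#'   `level`, `start_s`, `end_s`, `dwell_ms`), `n_samples`,
#'   `sampling_rate_hz`.
#' @export
idealize <- function(trace, levels, config = analysis_config()) {
  stopifnot(inherits(levels, "conductance_levels"))
  x <- trace$current_pA
  fs <- trace$protocol$sampling_rate_hz
  mu <- levels$levels$current_pA
  if (length(mu) == 1L) {
    lv <- rep(1L, length(x))
  } else {
    lv <- hysteresis_assign(x, mu, config$hysteresis_fraction)
  }
  min_len <- max(1L, round(config$min_stable_dwell_ms / 1000 * fs))
  r <- rle(lv)
  # iteratively merge sub-threshold dwells (shortest first) into the
  # flanking level with nearer current
  repeat {
    if (length(r$lengths) <= 1L) break
    short <- which(r$lengths < min_len)
    if (!length(short)) break
    i <- short[which.min(r$lengths[short])]
    if (i == 1L) {
      tgt <- r$values[2L]
    } else if (i == length(r$values)) {
      tgt <- r$values[length(r$values) - 1L]
    } else {
      dl <- abs(mu[r$values[i]] - mu[r$values[i - 1L]])
      dr <- abs(mu[r$values[i]] - mu[r$values[i + 1L]])
      tgt <- if (dl <= dr) r$values[i - 1L] else r$values[i + 1L]
    }
    r$values[i] <- tgt
    # recombine adjacent equal runs
    keep <- c(TRUE, r$values[-1L] != r$values[-length(r$values)])
    r <- list(lengths = as.integer(tapply(r$lengths, cumsum(keep), sum)),
              values = r$values[keep])
  }
  ends <- cumsum(r$lengths)
  starts <- c(1L, ends[-length(ends)] + 1L)
  seg <- data.frame(start = starts, end = ends + 1L,   # half-open
                    level = levels$levels$level[r$values])
  seg$start_s <- (seg$start - 1L) / fs
  seg$end_s <- (seg$end - 1L) / fs
  seg$dwell_ms <- (seg$end - seg$start) / fs * 1000
  structure(list(segments = seg, n_samples = length(x),
                 sampling_rate_hz = fs),
            class = "ptp_idealization")
}

#' @export
print.ptp_idealization <- function(x, ...) {
  cat("<ptp_idealization> ", nrow(x$segments), " segments over ",
      x$n_samples, " samples\n", sep = "")
  print(utils::head(x$segments, 10))
  if (nrow(x$segments) > 10) cat("  ...\n")
  invisible(x)
}

#' Per-sample level ids of an idealization
#'
#' @param ideal a `ptp_idealization`.
#' @return integer vector of level ids (0 = baseline), one per sample.
#' @export
idealized_levels <- function(ideal) {
  rep(ideal$segments$level, ideal$segments$end - ideal$segments$start)
}

#' Offset (baseline drift) correction
#'
#' Fits a piecewise-linear baseline through the mean current of each
#' closed-state dwell (linear interpolation between dwell midpoints,
#' constant extrapolation at the ends) and subtracts it from the trace.
#' With fewer than two closed dwells the baseline is the constant
#' closed-level current. This single correction is reused by every
#' conductance statistic.
#'
#' @param trace a `ptp_trace`.
#' @param ideal a [idealize()] result.
#' @param levels the [extract_levels()] result used for `ideal`.
#' @return numeric vector of baseline-corrected current, pA.
#' @export
correct_baseline <- function(trace, ideal, levels) {
  x <- trace$current_pA
  t <- trace_times(trace)
  seg <- ideal$segments
  closed <- seg[seg$level == 0L, , drop = FALSE]
  if (nrow(closed) == 0L)
    return(x - levels$baseline_current_pA)
  mid_t <- (closed$start_s + closed$end_s) / 2
  mid_mu <- vapply(seq_len(nrow(closed)), function(i)
    mean(x[closed$start[i]:(closed$end[i] - 1L)]), 0)
  if (nrow(closed) == 1L) return(x - mid_mu)
  base <- stats::approx(mid_t, mid_mu, xout = t, rule = 2)$y
  x - base
}

#' Detect level transitions
#'
#' Emits one event per idealized segment boundary. The transition duration
#' is measured on the filtered current as the time between the 10% and 90%
#' crossings of the inter-level gap around the boundary; an instantaneous
#' gating step filtered at 500 Hz measures about 0.7 ms, while genuinely
#' slow conductance changes measure their ramp time. Events carry the
#' signed conductance change `delta_g_pS`. No duration filtering happens
#' here; the <10 ms stability rule is applied by [compute_gmax()].
#'
#' @param ideal a [idealize()] result.
#' @param trace the `ptp_trace` it came from.
#' @param levels the [extract_levels()] result used for `ideal`.
#' @return data.frame with columns `time_s`, `duration_ms`, `from_level`,
#'   `to_level`, `delta_g_pS`.
#' @export
detect_transitions <- function(ideal, trace, levels) {
  seg <- ideal$segments
  lev <- levels$levels
  out <- data.frame(time_s = numeric(0), duration_ms = numeric(0),
                    from_level = integer(0), to_level = integer(0),
                    delta_g_pS = numeric(0))
  if (nrow(seg) < 2L) return(out)
  x <- trace$current_pA
  fs <- trace$protocol$sampling_rate_hz
  g <- function(l) lev$conductance_pS[match(l, lev$level)]
  mu <- function(l) lev$current_pA[match(l, lev$level)]
  events <- vector("list", nrow(seg) - 1L)
  for (i in seq_len(nrow(seg) - 1L)) {
    b <- seg$end[i]                       # first sample of the new segment
    from <- seg$level[i]; to <- seg$level[i + 1L]
    mf <- mu(from); mt <- mu(to)
    delta <- mt - mf
    th10 <- mf + 0.1 * delta
    th90 <- mf + 0.9 * delta
    s <- sign(delta)
    lo <- max(seg$start[i], b - as.integer(0.1 * fs),
              floor((seg$start[i] + seg$end[i]) / 2))
    hi <- min(seg$end[i + 1L] - 1L, b + as.integer(0.1 * fs),
              ceiling((seg$start[i + 1L] + seg$end[i + 1L]) / 2))
    w <- x[lo:hi]
    rel <- seq_along(w)
    past90 <- which(s * (w - th90) >= 0)
    if (length(past90)) {
      j90 <- past90[1]
      before10 <- which(s * (w[seq_len(j90)] - th10) <= 0)
      j10 <- if (length(before10)) before10[length(before10)] else 1L
      dur_ms <- (j90 - j10) / fs * 1000
    } else {
      dur_ms <- (hi - lo) / fs * 1000     # never completed within window
    }
    events[[i]] <- data.frame(time_s = (b - 1L) / fs,
                              duration_ms = dur_ms,
                              from_level = from, to_level = to,
                              delta_g_pS = g(to) - g(from))
  }
  do.call(rbind, events)
}
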