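#' Zero-phase Gaussian low-pass filter
#'
#' Symmetric FIR Gaussian kernel whose frequency response is -3 dB at
#' `cutoff_hz` (sigma_t = sqrt(ln 2) / (2 pi f_c), i.e. a 10-90% step rise
#' time of about 0.66 ms at 500 Hz). Edges are handled by replicating the
#' first and last sample, so a constant segment keeps its mean exactly and
#' the filter is transparent to DC.
#'
#' @param x numeric signal.
#' @param sampling_rate_hz sampling rate, Hz.
#' @param cutoff_hz -3 dB cutoff, Hz.
#' @return filtered signal, same length as `x`.
#' @export
lowpass_gaussian <- function(x, sampling_rate_hz, cutoff_hz) {
  sigma <- sqrt(log(2)) / (2 * pi * cutoff_hz) * sampling_rate_hz  # samples
  hw <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- stats::dnorm(seq(-hw, hw), sd = sigma)
  k <- k / sum(k)
  n <- length(x)
  padded <- c(rep(x[1], hw), x, rep(x[n], hw))
  y <- stats::filter(padded, k, method = "convolution", sides = 2)
  as.numeric(y[(hw + 1L):(hw + n)])
}

# Exact-jump CTMC path over [0, duration): exponential holding times,
# piecewise-constant generator across intervention epochs (interventions
# multiply the base rates from their time onward, cumulatively). Returns
# segments (start_s, end_s, state). Memorylessness lets the dwell in
# progress at an epoch boundary be truncated and resampled under the new
# generator.
simulate_ctmc_path <- function(model, duration_s, interventions = list()) {
  iv <- interventions[order(vapply(interventions, `[[`, 0, "time_s"))]
  iv <- Filter(function(i) !is.null(i$rate_multipliers), iv)
  breaks <- unique(c(0, vapply(iv, `[[`, 0, "time_s"), duration_s))
  breaks <- breaks[breaks <= duration_s]
  if (breaks[length(breaks)] < duration_s) breaks <- c(breaks, duration_s)
  n_states <- nrow(model$states)
  base <- model$rates
  diag(base) <- 0

  starts <- numeric(0); states <- integer(0)
  s <- model$initial_state
  t <- 0
  starts <- c(starts, 0); states <- c(states, s)
  for (e in seq_len(length(breaks) - 1L)) {
    t0 <- breaks[e]; t1 <- breaks[e + 1L]
    q <- base
    for (ivn in iv)
      if (ivn$time_s <= t0) q <- q * ivn$rate_multipliers
    t <- max(t, t0)
    repeat {
      rate_out <- sum(q[s, ])
      if (rate_out <= 0) { t <- t1; break }
      dwell <- stats::rexp(1L, rate_out)
      if (t + dwell >= t1) { t <- t1; break }
      t <- t + dwell
      s <- sample.int(n_states, 1L, prob = q[s, ])
      starts <- c(starts, t); states <- c(states, s)
    }
  }
  # collapse self-jumps (none expected) and emit segments
  data.frame(start_s = starts,
             end_s = c(starts[-1L], duration_s),
             state = states)
}

#' Simulate a single-channel current recording
#'
#' Samples an exact-jump continuous-time Markov path from the gating model,
#' rasterizes it onto the sampling grid, converts state conductance to
#' current as `baseline + g * V_h / 1000 + drift * t + noise` (pS x mV /
#' 1000 = pA), and low-pass filters at the protocol cutoff. The true state
#' path is attached for oracle tests. Identical `(model, protocol,
#' interventions, seed)` produce bit-identical traces.
#'
#' @param model a [channel_model()].
#' @param protocol a [recording_protocol()].
#' @param interventions list of [intervention()]s; each must fall within
#'   the trace duration. Interventions with a `rate_multipliers` matrix
#'   change the gating from their time onward; the matrix dimension must
#'   match the model.
#' @param seed integer seed; required for reproducibility.
#' @return object of class `ptp_trace`: list with `protocol`, `current_pA`
#'   (filtered), `current_raw_pA` (pre-filter), `interventions`, and
#'   `truth` (list with `path` segments and `conductance_pS` per state).
#' @export
simulate_channel_trace <- function(model, protocol, interventions = list(),
                                   seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (!inherits(model, "channel_model")) stop("`model` must be a channel_model",
                                              call. = FALSE)
  if (!inherits(protocol, "recording_protocol"))
    stop("`protocol` must be a recording_protocol", call. = FALSE)
  if (inherits(interventions, "intervention")) interventions <- list(interventions)
  for (ivn in interventions) {
    if (!inherits(ivn, "intervention")) stop("interventions must be intervention objects",
                                             call. = FALSE)
    if (ivn$time_s >= protocol$duration_s)
      stop("intervention \"", ivn$label, "\" at ", ivn$time_s,
           " s lies beyond the trace duration ", protocol$duration_s, " s",
           call. = FALSE)
    if (!is.null(ivn$rate_multipliers) &&
        nrow(ivn$rate_multipliers) != nrow(model$states))
      stop("rate_multipliers dimension does not match the model", call. = FALSE)
  }
  fs <- protocol$sampling_rate_hz
  n <- round(protocol$duration_s * fs)
  g <- model$states$conductance_pS

  with_seed(seed, {
    path <- simulate_ctmc_path(model, protocol$duration_s, interventions)
    t_samp <- (seq_len(n) - 1L) / fs
    seg_idx <- findInterval(t_samp, path$start_s)
    state <- path$state[seg_idx]
    raw <- model$baseline_current +
      g[state] * protocol$holding_potential_mV / 1000 +
      model$drift_slope * t_samp +
      stats::rnorm(n, 0, model$noise_sd)
    filtered <- lowpass_gaussian(raw, fs, protocol$filter_cutoff_hz)
    new_trace(protocol, filtered, interventions,
              raw = raw,
              truth = list(path = path, conductance_pS = g,
                           state_path = state))
  })
}

#' Construct a trace from a current vector
#'
#' Wraps an existing current record (e.g. assembled in code or imported
#' from another acquisition system) as a `ptp_trace` so it can be fed to
#' the analysis functions. The protocol duration is taken from the sample
#' count.
#'
#' @param current_pA numeric current samples, pA.
#' @param protocol a [recording_protocol()]; its `duration_s` is replaced
#'   by `length(current_pA) / sampling_rate_hz`.
#' @param interventions list of [intervention()]s.
#' @return a `ptp_trace`.
#' @export
ptp_trace <- function(current_pA, protocol, interventions = list()) {
  protocol$duration_s <- length(current_pA) / protocol$sampling_rate_hz
  new_trace(protocol, as.numeric(current_pA), interventions)
}

new_trace <- function(protocol, current_pA, interventions = list(),
                      raw = NULL, truth = NULL) {
  structure(list(protocol = protocol,
                 current_pA = current_pA,
                 current_raw_pA = raw,
                 interventions = interventions,
                 truth = truth),
            class = "ptp_trace")
}

#' @export
print.ptp_trace <- function(x, ...) {
  p <- x$protocol
  cat("<ptp_trace> ", length(x$current_pA), " samples, ", p$duration_s,
      " s @ ", p$sampling_rate_hz, " Hz, V_h = ", p$holding_potential_mV,
      " mV, filtered at ", p$filter_cutoff_hz, " Hz\n", sep = "")
  for (ivn in x$interventions)
    cat("  intervention: ", ivn$label, " @ ", ivn$time_s, " s\n", sep = "")
  invisible(x)
}

#' Trace sample times
#'
#' @param trace a `ptp_trace`.
#' @return numeric vector of sample times, s.
#' @export
trace_times <- function(trace) {
  (seq_along(trace$current_pA) - 1L) / trace$protocol$sampling_rate_hz
}

#' Simulate a recording from a packaged preset
#'
#' Simulates one experiment from [make_preset()] under the default
#' recording protocol. To emulate the between-experiment dispersion of
#' reported conductances (means +/- SEM across experiments), the preset's
#' open-state conductances are jointly rescaled per seed by a factor drawn
#' from N(1, cv); the default cv of 0.1 gives a coefficient of variation
#' of about 10% across experiments.
#'
#' @param name preset name (see [make_preset()]).
#' @param seed integer seed.
#' @param protocol recording protocol; default 90 s at the standard
#'   mitoplast settings (blocker at 60 s leaves the 30-s pre-blocker
#'   window used by G_mean).
#' @param jitter_cv between-experiment conductance coefficient of
#'   variation; 0 disables jitter.
#' @return a `ptp_trace`; `trace$truth$jitter` records the scale factor
#'   and `trace$truth$targets` the preset targets.
#' @export
simulate_preset <- function(name, seed, protocol = recording_protocol(),
                            jitter_cv = 0.1) {
  preset <- make_preset(name)
  model <- preset$model
  fac <- 1
  if (jitter_cv > 0) {
    fac <- with_seed((seed * 7919 + 1) %% 2147483647, {
      f <- stats::rnorm(1L, 1, jitter_cv)
      max(f, 0.5)
    })
    model$states$conductance_pS <- model$states$conductance_pS * fac
  }
  iv <- Filter(function(i) i$time_s < protocol$duration_s, preset$interventions)
  trace <- simulate_channel_trace(model, protocol, iv, seed)
  trace$truth$jitter <- fac
  trace$truth$targets <- preset$targets
  trace$truth$preset <- name
  trace
}
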