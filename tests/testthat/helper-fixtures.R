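# Shared in-code fixtures: small models and hand-built traces with exact
# known structure, used as oracles throughout the suite.

two_state_model <- function(g_pS = 800, k_open = 5, k_close = 5,
                            noise_sd = 0.5, drift = 0) {
  channel_model(
    states = data.frame(label = c("closed", "open"),
                        conductance_pS = c(0, g_pS)),
    rates = matrix(c(0, k_open, k_close, 0), 2, 2, byrow = TRUE),
    noise_sd = noise_sd, drift_slope = drift)
}

# piecewise-constant trace from (level current pA, dwell s) pairs
step_trace <- function(currents_pA, dwells_s, fs = 10000,
                       protocol = recording_protocol(sampling_rate_hz = fs)) {
  x <- unlist(mapply(function(cur, dw) rep(cur, round(dw * fs)),
                     currents_pA, dwells_s, SIMPLIFY = FALSE))
  ptp_trace(x, protocol)
}

manual_fit <- function(weights, means, sds) {
  comp <- data.frame(weight = weights, mean_pA = means, sd_pA = sds)
  comp <- comp[order(comp$mean_pA), ]
  rownames(comp) <- NULL
  structure(list(components = comp, k = nrow(comp),
                 log_likelihood = NA_real_, bic = NA_real_, n = 1000L),
            class = "mixture_fit")
}

# analysis config whose stability dwell is below one sample: no merging,
# used for exact noise-free recovery tests
exact_config <- function(fs = 10000) {
  analysis_config(min_stable_dwell_ms = 1000 / fs / 2)
}

# hand-built swelling series with a prescribed post-Ca2+ plateau
make_absorbance <- function(a_eval, a0 = 1.0, a_ala = 0.4,
                            ca_time = 60, ala_time = 780) {
  t <- seq(0, 900, by = 5)
  a <- rep(a0, length(t))
  a[t >= ca_time] <- a_eval
  a[t >= ala_time] <- a_ala
  structure(data.frame(time_s = t, a540 = a),
            ca_time_s = ca_time, ala_time_s = ala_time,
            class = c("absorbance_series", "data.frame"))
}
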