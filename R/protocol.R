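#' Patch-clamp recording protocol
#'
#' Defaults match the mitoplast recording conditions used throughout:
#' constant holding potential +20 mV, 10 kHz sampling, 500 Hz low-pass
#' filtering.
#'
#' @param holding_potential_mV constant holding potential V_h, mV (non-zero).
#' @param sampling_rate_hz sampling rate, Hz.
#' @param filter_cutoff_hz -3 dB cutoff of the low-pass filter, Hz; must be
#'   below the Nyquist frequency.
#' @param duration_s recorded duration, s.
#' @return object of class `recording_protocol`.
#' @export
recording_protocol <- function(holding_potential_mV = 20,
                               sampling_rate_hz = 10000,
                               filter_cutoff_hz = 500,
                               duration_s = 90) {
  if (holding_potential_mV == 0)
    stop("holding potential must be non-zero (conductance = current / V_h)",
         call. = FALSE)
  if (sampling_rate_hz <= 0 || duration_s <= 0 || filter_cutoff_hz <= 0)
    stop("sampling rate, filter cutoff and duration must be positive",
         call. = FALSE)
  if (filter_cutoff_hz >= sampling_rate_hz / 2)
    stop("filter_cutoff_hz must be below the Nyquist frequency ",
         sampling_rate_hz / 2, " Hz", call. = FALSE)
  structure(list(holding_potential_mV = holding_potential_mV,
                 sampling_rate_hz = sampling_rate_hz,
                 filter_cutoff_hz = filter_cutoff_hz,
                 duration_s = duration_s),
            class = "recording_protocol")
}

#' Mid-trace intervention (blocker or agonist addition)
#'
#' An intervention multiplies the model's transition rates from `time_s`
#' onward: `rate_multipliers[i, j]` scales the rate of the ordered
#' transition i -> j. A multiplier of 0 abolishes the transition; the
#' all-zero matrix freezes the gating path.
#'
#' @param time_s time of addition, s.
#' @param label text label (e.g. `"CsA"`, `"BKA"`, `"Sr2+"`, `"Ba2+"`,
#'   `"MgADP"`, `"ATR"`).
#' @param rate_multipliers square matrix of non-negative
#'   per-ordered-state-pair factors, or `NULL` for an annotation-only
#'   intervention (as read from trace files, where only label and time
#'   are stored).
#' @return object of class `intervention`.
#' @export
intervention <- function(time_s, label, rate_multipliers = NULL) {
  stopifnot(is.numeric(time_s), length(time_s) == 1L, time_s >= 0,
            is.character(label), length(label) == 1L)
  if (!is.null(rate_multipliers)) {
    rate_multipliers <- as.matrix(rate_multipliers)
    if (nrow(rate_multipliers) != ncol(rate_multipliers))
      stop("rate_multipliers must be square", call. = FALSE)
    if (any(!is.finite(rate_multipliers)) || any(rate_multipliers < 0))
      stop("rate multipliers must be finite and >= 0", call. = FALSE)
  }
  structure(list(time_s = time_s, label = label,
                 rate_multipliers = rate_multipliers),
            class = "intervention")
}

#' Blocking intervention for a model
#'
#' Convenience constructor for a channel blocker: abolishes every
#' transition into a higher-conductance state (multiplier 0 on openings),
#' so the channel drains into the closed state and stays there. This
#' matches the observed phenomenology where pore closure rapidly follows
#' blocker addition.
#'
#' @param model the [channel_model()] the multipliers refer to.
#' @param time_s time of addition, s.
#' @param label blocker label.
#' @return an [intervention()].
#' @export
block_intervention <- function(model, time_s, label = "blocker") {
  g <- model$states$conductance_pS
  n <- length(g)
  m <- matrix(1, n, n)
  m[outer(g, g, `<`)] <- 0   # kill transitions toward higher conductance
  intervention(time_s, label, m)
}

# Evaluate code with a temporarily seeded RNG, restoring the caller's
# RNG state afterwards so simulations never disturb the session stream.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
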