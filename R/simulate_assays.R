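assert_pos <- function(...) {
  vals <- c(...)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("rates, amplitudes and concentrations must be finite and >= 0",
         call. = FALSE)
}

#' Swelling-assay simulation parameters
#'
#' Parameters of the light-scattering (absorbance at 540 nm) swelling
#' assay: a Ca2+ bolus triggers permeability-transition-driven swelling
#' (exponential absorbance decay), and alamethicin at the end of the run
#' collapses absorbance to the maximal-swelling floor.
#'
#' @param a0 initial absorbance, a.u.
#' @param swollen_amplitude asymptotic Ca2+-induced absorbance drop, a.u.
#' @param rate_constant swelling rate constant, 1/s.
#' @param ca_time_s time of the Ca2+ bolus, s.
#' @param ala_time_s time of alamethicin addition, s (must exceed
#'   `ca_time_s`).
#' @param ala_floor absorbance plateau after alamethicin, a.u.
#' @param noise_sd measurement noise, a.u.
#' @param duration_s assay duration, s.
#' @param dt_s sampling interval, s.
#' @return object of class `swelling_params`.
#' @export
swelling_params <- function(a0 = 1.0, swollen_amplitude = 0.45,
                            rate_constant = 0.01, ca_time_s = 60,
                            ala_time_s = 780, ala_floor = 0.4,
                            noise_sd = 0.004, duration_s = 900, dt_s = 5) {
  assert_pos(a0, swollen_amplitude, rate_constant, ca_time_s, ala_time_s,
             ala_floor, noise_sd, duration_s, dt_s)
  if (ala_time_s <= ca_time_s)
    stop("alamethicin must be added after the Ca2+ bolus", call. = FALSE)
  structure(as.list(environment()), class = "swelling_params")
}

#' Simulate a swelling absorbance series
#'
#' Absorbance stays at `a0` before the Ca2+ bolus, then (only with Ca2+)
#' decays exponentially toward `a0 - swollen_amplitude`, and steps to the
#' alamethicin floor at `ala_time_s`; white noise is added throughout.
#'
#' @param params a [swelling_params()].
#' @param with_ca whether the Ca2+ bolus is actually added.
#' @param seed integer seed.
#' @return an `absorbance_series`: data.frame (`time_s`, `a540`) with
#'   attributes `ca_time_s` (or `NA` without Ca2+), `ala_time_s`, `truth`.
#' @export
simulate_swelling <- function(params = swelling_params(), with_ca = TRUE,
                              seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  stopifnot(inherits(params, "swelling_params"))
  t <- seq(0, params$duration_s, by = params$dt_s)
  a <- rep(params$a0, length(t))
  if (with_ca) {
    idx <- t >= params$ca_time_s
    a[idx] <- params$a0 - params$swollen_amplitude *
      (1 - exp(-params$rate_constant * (t[idx] - params$ca_time_s)))
  }
  a[t >= params$ala_time_s] <- params$ala_floor
  a <- a + with_seed(seed, stats::rnorm(length(t), 0, params$noise_sd))
  structure(data.frame(time_s = t, a540 = a),
            ca_time_s = if (with_ca) params$ca_time_s else NA_real_,
            ala_time_s = params$ala_time_s,
            truth = list(params = params, with_ca = with_ca),
            class = c("absorbance_series", "data.frame"))
}

#' Calcium-retention-capacity simulation parameters
#'
#' A suspension of isolated mitochondria receives a train of Ca2+ pulses
#' monitored by an extramitochondrial Ca2+ indicator (Calcium Green):
#' each pulse spikes the fluorescence, uptake returns it toward baseline,
#' and once cumulative retained Ca2+ exceeds the capacity the pore opens
#' and all retained Ca2+ is released.
#'
#' @param capacity_uM total Ca2+ the suspension can retain, uM.
#' @param pulse_size_uM Ca2+ added per pulse, uM.
#' @param pulse_interval_s time between pulses, s.
#' @param uptake_rate uptake rate constant, 1/s.
#' @param protein_mg_ml mitochondrial protein concentration, mg/ml.
#' @param noise_sd fluorescence noise, a.u.
#' @param f0 indicator baseline fluorescence, a.u.
#' @param f_per_uM fluorescence gain, a.u. per uM extramitochondrial Ca2+.
#' @param release_rate rate of the release rise after pore opening, 1/s.
#' @param dt_s sampling interval, s.
#' @param start_s time of the first pulse, s.
#' @return object of class `crc_params`.
#' @export
crc_params <- function(capacity_uM = 100, pulse_size_uM = 2.5,
                       pulse_interval_s = 60, uptake_rate = 0.1,
                       protein_mg_ml = 0.4, noise_sd = 0.8,
                       f0 = 50, f_per_uM = 10, release_rate = 0.05,
                       dt_s = 1, start_s = 60) {
  assert_pos(capacity_uM, pulse_size_uM, pulse_interval_s, uptake_rate,
             protein_mg_ml, noise_sd, f0, f_per_uM, release_rate, dt_s,
             start_s)
  if (pulse_size_uM <= 0) stop("pulse size must be positive", call. = FALSE)
  structure(as.list(environment()), class = "crc_params")
}

#' Simulate a calcium-retention-capacity fluorescence series
#'
#' Pulses are delivered every `pulse_interval_s` starting at `start_s`.
#' A pulse is taken up (extramitochondrial Ca2+ decays exponentially at
#' `uptake_rate`) as long as cumulative retained Ca2+ would not exceed
#' the capacity; the first pulse that would exceed it triggers release:
#' uptake stops and all retained Ca2+ returns to the medium, so
#' fluorescence rises monotonically. With capacity 0 the first pulse is
#' never taken up. Enough pulses are delivered to exceed the capacity by
#' three pulses.
#'
#' @param params a [crc_params()].
#' @param seed integer seed.
#' @return a `fluorescence_series`: data.frame (`time_s`, `fluorescence`)
#'   with attributes `pulse_times_s`, `truth` (list with
#'   `retained_pulses`, `release_pulse_time_s`, `params`).
#' @export
simulate_crc <- function(params = crc_params(), seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  stopifnot(inherits(params, "crc_params"))
  n_retained_true <- floor(params$capacity_uM / params$pulse_size_uM)
  n_pulses <- n_retained_true + 3L
  pulse_times <- params$start_s + (seq_len(n_pulses) - 1L) * params$pulse_interval_s
  duration <- pulse_times[n_pulses] + 3 * params$pulse_interval_s
  t <- seq(0, duration, by = params$dt_s)
  extra <- numeric(length(t))      # extramitochondrial Ca2+, uM
  e <- 0; retained <- 0; released <- FALSE; delivered <- 0
  release_time <- NA_real_
  total_added <- 0
  for (i in seq_along(t)) {
    due <- which(pulse_times <= t[i])
    while (delivered < length(due)) {
      delivered <- delivered + 1L
      total_added <- total_added + params$pulse_size_uM
      if (!released && total_added > params$capacity_uM) {
        released <- TRUE
        release_time <- pulse_times[delivered]
        e <- e + params$pulse_size_uM
      } else if (!released) {
        e <- e + params$pulse_size_uM
      } else {
        e <- e + params$pulse_size_uM
      }
    }
    if (!released) {
      up <- e * (1 - exp(-params$uptake_rate * params$dt_s))
      e <- e - up
      retained <- retained + up
    } else {
      # released Ca2+ re-equilibrates into the medium
      e <- e + (retained - 0) * (1 - exp(-params$release_rate * params$dt_s)) *
        (retained > 0)
      retained <- retained * exp(-params$release_rate * params$dt_s)
    }
    extra[i] <- e
  }
  f <- params$f0 + params$f_per_uM * extra +
    with_seed(seed, stats::rnorm(length(t), 0, params$noise_sd))
  structure(data.frame(time_s = t, fluorescence = f),
            pulse_times_s = pulse_times,
            truth = list(retained_pulses = n_retained_true,
                         release_pulse_time_s = release_time,
                         params = params),
            class = c("fluorescence_series", "data.frame"))
}

#' Live-cell timecourse simulation parameters
#'
#' Per-ROI calcein and TMRM fluorescence of cells undergoing a
#' permeability transition after an agonist addition: after
#' `addition_time_s` each ROI independently draws an exponential onset
#' delay, then both channels decay exponentially toward their floors.
#' A protective drug multiplies the mean onset delay by its protection
#' factor (`Inf` = complete protection).
#'
#' @param n_rois number of ROIs.
#' @param calcein_baseline,tmrm_baseline mean baseline intensities, a.u.
#' @param roi_cv between-ROI coefficient of variation of the baselines.
#' @param background_calcein,background_tmrm camera background, a.u.
#' @param addition_time_s agonist addition time, s.
#' @param onset_mean_s mean permeability-transition onset delay after
#'   addition, s.
#' @param calcein_decay,tmrm_decay post-onset decay rates, 1/s.
#' @param calcein_floor,tmrm_floor fluorescence floors as fractions of
#'   baseline.
#' @param protection_factors named numeric vector of onset-delay
#'   multipliers per drug label; must include `"none"`.
#' @param sampling_interval_s sampling interval, s.
#' @param duration_s recording duration, s.
#' @param noise_sd measurement noise, a.u.
#' @return object of class `timecourse_params`.
#' @export
timecourse_params <- function(n_rois = 80, calcein_baseline = 1000,
                              tmrm_baseline = 800, roi_cv = 0.15,
                              background_calcein = 50, background_tmrm = 40,
                              addition_time_s = 120, onset_mean_s = 40,
                              calcein_decay = 0.02, tmrm_decay = 0.012,
                              calcein_floor = 0.15, tmrm_floor = 0.2,
                              protection_factors = c(none = 1, CsA = 30,
                                                     BKA = 12, ATR = 0.3),
                              sampling_interval_s = 30, duration_s = 720,
                              noise_sd = 5) {
  if (n_rois < 1) stop("need at least one ROI", call. = FALSE)
  assert_pos(calcein_baseline, tmrm_baseline, roi_cv, background_calcein,
             background_tmrm, addition_time_s, onset_mean_s, calcein_decay,
             tmrm_decay, calcein_floor, tmrm_floor, sampling_interval_s,
             duration_s, noise_sd)
  if (!("none" %in% names(protection_factors)))
    stop("protection_factors must include a \"none\" entry", call. = FALSE)
  if (any(protection_factors < 0))
    stop("protection factors must be >= 0", call. = FALSE)
  if (duration_s <= addition_time_s)
    stop("duration must extend past the addition time", call. = FALSE)
  structure(as.list(environment()), class = "timecourse_params")
}

#' Simulate per-ROI calcein/TMRM timecourses
#'
#' @param params a [timecourse_params()].
#' @param drug drug label; must name an entry of
#'   `params$protection_factors`.
#' @param seed integer seed.
#' @return a `roi_timecourse_set`: long data.frame (`roi`, `time_s`,
#'   `calcein`, `tmrm`) with attributes `addition_time_s`,
#'   `background` (named: calcein, tmrm), `condition` (the drug label),
#'   `truth` (onset delays and params).
#' @export
simulate_cell_timecourse <- function(params = timecourse_params(),
                                     drug = "none", seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  stopifnot(inherits(params, "timecourse_params"))
  if (!(drug %in% names(params$protection_factors)))
    stop("unknown drug label \"", drug, "\"; known: ",
         paste(names(params$protection_factors), collapse = ", "),
         call. = FALSE)
  pf <- params$protection_factors[[drug]]
  t <- seq(0, params$duration_s, by = params$sampling_interval_s)
  with_seed(seed, {
    base_cal <- params$calcein_baseline *
      pmax(0.2, stats::rnorm(params$n_rois, 1, params$roi_cv))
    base_tmrm <- params$tmrm_baseline *
      pmax(0.2, stats::rnorm(params$n_rois, 1, params$roi_cv))
    onset <- if (is.infinite(pf)) rep(Inf, params$n_rois)
             else if (pf == 0) rep(0, params$n_rois)
             else stats::rexp(params$n_rois, rate = 1 / (params$onset_mean_s * pf))
    rows <- vector("list", params$n_rois)
    for (r in seq_len(params$n_rois)) {
      t_on <- params$addition_time_s + onset[r]
      dtp <- pmax(0, t - t_on)
      cal <- base_cal[r] * (params$calcein_floor +
        (1 - params$calcein_floor) * exp(-params$calcein_decay * dtp))
      tm <- base_tmrm[r] * (params$tmrm_floor +
        (1 - params$tmrm_floor) * exp(-params$tmrm_decay * dtp))
      rows[[r]] <- data.frame(
        roi = r, time_s = t,
        calcein = cal + params$background_calcein +
          stats::rnorm(length(t), 0, params$noise_sd),
        tmrm = tm + params$background_tmrm +
          stats::rnorm(length(t), 0, params$noise_sd))
    }
    structure(do.call(rbind, rows),
              addition_time_s = params$addition_time_s,
              background = c(calcein = params$background_calcein,
                             tmrm = params$background_tmrm),
              condition = drug,
              truth = list(onset_delays_s = onset, params = params,
                           protection_factor = pf),
              class = c("roi_timecourse_set", "data.frame"))
  })
}

#' OCR (Seahorse-style) simulation parameters
#'
#' Plateau oxygen consumption rates around the standard injection
#' sequence oligomycin -> FCCP -> rotenone -> antimycin A.
#'
#' @param basal basal OCR plateau, pmol O2/min.
#' @param nonmito rotenone/antimycin-insensitive OCR, pmol O2/min.
#' @param oligo_frac fraction of mitochondrial respiration that is
#'   oligomycin-sensitive (ATP-synthesis linked).
#' @param fccp_factor maximal respiration as a multiple of basal
#'   mitochondrial OCR.
#' @param oligo_time_s,fccp_time_s,rot_time_s,aa_time_s injection times,
#'   s (strictly increasing).
#' @param fccp_nM FCCP concentration metadata, nM.
#' @param protein_ug protein content used for normalization.
#' @param noise_sd measurement noise.
#' @param dt_s sampling interval, s.
#' @param duration_s assay duration, s.
#' @return object of class `ocr_params`.
#' @export
ocr_params <- function(basal = 100, nonmito = 10, oligo_frac = 0.6,
                       fccp_factor = 1.5, oligo_time_s = 1080,
                       fccp_time_s = 2160, rot_time_s = 3240,
                       aa_time_s = 3360, fccp_nM = 100, protein_ug = 1,
                       noise_sd = 1.5, dt_s = 30, duration_s = 4500) {
  assert_pos(basal, nonmito, oligo_frac, fccp_factor, oligo_time_s,
             fccp_time_s, rot_time_s, aa_time_s, protein_ug, noise_sd,
             dt_s, duration_s)
  times <- c(oligo_time_s, fccp_time_s, rot_time_s, aa_time_s)
  if (any(diff(times) <= 0))
    stop("injection times must be strictly increasing ",
         "(oligomycin, FCCP, rotenone, antimycin A)", call. = FALSE)
  if (duration_s <= aa_time_s)
    stop("duration must extend past the antimycin A injection", call. = FALSE)
  structure(as.list(environment()), class = "ocr_params")
}

#' Simulate an OCR series
#'
#' @param params an [ocr_params()].
#' @param seed integer seed.
#' @return an `ocr_series`: data.frame (`time_s`, `ocr`) with attributes
#'   `injections_s` (named: oligomycin, fccp, rotenone, antimycin_a),
#'   `protein_ug`, `fccp_nM`, `truth`.
#' @export
simulate_ocr <- function(params = ocr_params(), seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  stopifnot(inherits(params, "ocr_params"))
  t <- seq(0, params$duration_s, by = params$dt_s)
  mito <- params$basal - params$nonmito
  level <- rep(params$basal, length(t))
  level[t >= params$oligo_time_s] <- params$nonmito + mito * (1 - params$oligo_frac)
  level[t >= params$fccp_time_s] <- params$nonmito + mito * params$fccp_factor
  level[t >= params$rot_time_s] <- params$nonmito + 0.3 * mito  # complex I off
  level[t >= params$aa_time_s] <- params$nonmito
  ocr <- level + with_seed(seed, stats::rnorm(length(t), 0, params$noise_sd))
  structure(data.frame(time_s = t, ocr = ocr),
            injections_s = c(oligomycin = params$oligo_time_s,
                             fccp = params$fccp_time_s,
                             rotenone = params$rot_time_s,
                             antimycin_a = params$aa_time_s),
            protein_ug = params$protein_ug,
            fccp_nM = params$fccp_nM,
            truth = list(params = params),
            class = c("ocr_series", "data.frame"))
}
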