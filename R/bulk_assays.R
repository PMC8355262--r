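series_attr <- function(series, name) {
  v <- attr(series, name, exact = TRUE)
  if (is.null(v)) stop("series is missing the `", name, "` attribute",
                       call. = FALSE)
  v
}

#' Fraction of swollen mitochondria
#'
#' Normalizes the Ca2+-induced absorbance drop by the maximal
#' (alamethicin-induced) drop:
#' `fraction = (A_baseline - A_eval) / (A_baseline - A_ala)`, where
#' `A_baseline` is the mean pre-Ca2+ absorbance, `A_eval` the absorbance
#' `t_eval_offset_s` after the Ca2+ bolus (default 540 s, i.e. about
#' 9 min), and `A_ala` the post-alamethicin plateau (mean of the last
#' three samples). The fraction is clamped to the unit interval and is invariant
#' under affine rescaling of the absorbance values.
#'
#' @param series an `absorbance_series` (see [simulate_swelling()] or
#'   [read_series()]): columns `time_s`, `a540`, attributes `ca_time_s`,
#'   `ala_time_s`.
#' @param t_eval_offset_s evaluation time after the Ca2+ bolus, s.
#' @return object of class `swelling_result`: list with `fraction`,
#'   `t_eval_s`, `a_baseline`, `a_eval`, `a_ala`.
#' @export
swollen_fraction <- function(series, t_eval_offset_s = 540) {
  ca_time <- series_attr(series, "ca_time_s")
  ala_time <- series_attr(series, "ala_time_s")
  if (is.na(ca_time))
    stop("series has no Ca2+ addition; the swollen fraction is defined ",
         "relative to the Ca2+ bolus", call. = FALSE)
  t <- series$time_s; a <- series$a540
  post_ala <- a[t > ala_time]
  if (length(post_ala) < 3L)
    stop("no alamethicin plateau: need at least 3 samples after ala_time",
         call. = FALSE)
  a_base <- mean(a[t < ca_time])
  a_ala <- mean(utils::tail(post_ala, 3L))
  t_eval <- min(ca_time + t_eval_offset_s, ala_time)
  a_eval <- stats::approx(t, a, xout = t_eval, rule = 2)$y
  if (a_base <= a_ala)
    stop("degenerate assay: baseline absorbance (", round(a_base, 4),
         ") does not exceed the alamethicin floor (", round(a_ala, 4), ")",
         call. = FALSE)
  frac <- (a_base - a_eval) / (a_base - a_ala)
  structure(list(fraction = min(1, max(0, frac)), t_eval_s = t_eval,
                 a_baseline = a_base, a_eval = a_eval, a_ala = a_ala),
            class = "swelling_result")
}

#' @export
print.swelling_result <- function(x, ...) {
  cat("<swelling_result> fraction ", round(x$fraction, 3), " at t = ",
      x$t_eval_s, " s (A0 ", round(x$a_baseline, 3), ", A_eval ",
      round(x$a_eval, 3), ", A_ala ", round(x$a_ala, 3), ")\n", sep = "")
  invisible(x)
}

#' Calcium retention capacity
#'
#' Counts how many Ca2+ pulses the suspension takes up before
#' permeability-transition-driven release. A pulse is retained when the
#' fluorescence returns below its pre-pulse baseline plus a tolerance
#' (3x the pre-assay noise standard deviation) before the next pulse;
#' retained pulses are counted from the first pulse up to the first
#' non-retained one. CRC is expressed per protein:
#' `retained_pulses * pulse_size_uM / protein_mg_ml` in nmol Ca2+ per mg.
#'
#' @param series a `fluorescence_series` with attribute `pulse_times_s`.
#' @param pulse_size_uM Ca2+ added per pulse, uM.
#' @param protein_mg_ml protein concentration, mg/ml.
#' @param tolerance_sigmas recovery tolerance in pre-assay noise sigmas.
#' @return object of class `crc_result`: list with `retained_pulses`,
#'   `crc_nmol_mg`, `release_time_s` (`NA` when no release is seen).
#' @export
crc <- function(series, pulse_size_uM = 2.5, protein_mg_ml = 0.4,
                tolerance_sigmas = 3) {
  pulses <- series_attr(series, "pulse_times_s")
  if (!length(pulses)) stop("series has no pulse timestamps", call. = FALSE)
  t <- series$time_s; f <- series$fluorescence
  pre <- f[t < pulses[1]]
  noise_sd <- if (length(pre) >= 3L) stats::sd(pre) else 0
  spike <- max(f) - stats::median(pre)
  tol <- tolerance_sigmas * noise_sd
  if (tol == 0) tol <- 0.01 * spike   # noiseless input: 1% of spike height
  bounds <- c(pulses, max(t) + 1)
  retained <- 0L
  release_time <- NA_real_
  for (k in seq_along(pulses)) {
    pre_k <- f[t < pulses[k]]
    base_k <- if (length(pre_k)) mean(utils::tail(pre_k, 3L)) else f[1]
    win <- f[t > pulses[k] & t < bounds[k + 1L]]
    if (length(win) && any(win <= base_k + tol)) {
      retained <- retained + 1L
    } else {
      release_time <- pulses[k]
      break
    }
  }
  structure(list(retained_pulses = retained,
                 crc_nmol_mg = retained * pulse_size_uM / protein_mg_ml,
                 release_time_s = release_time),
            class = "crc_result")
}

#' @export
print.crc_result <- function(x, ...) {
  cat("<crc_result> ", x$retained_pulses, " pulses retained, CRC ",
      round(x$crc_nmol_mg, 1), " nmol Ca2+/mg", sep = "")
  if (!is.na(x$release_time_s))
    cat(", release at ", x$release_time_s, " s", sep = "")
  cat("\n")
  invisible(x)
}

#' Oxygen-consumption-rate summary
#'
#' Non-mitochondrial respiration (the plateau after rotenone + antimycin A)
#' is subtracted from every rate, and rates are normalized to protein:
#' `basal = (mean pre-oligomycin - nonmito) / protein` and
#' `oligo_sensitive = basal - (mean post-oligomycin - nonmito) / protein`,
#' the ATP-synthesis-linked component. Plateau means use the last three
#' samples before the next injection (robust to injection transients).
#' Adding a constant to the whole series leaves both summaries unchanged.
#'
#' @param series an `ocr_series` with attributes `injections_s` (named
#'   `oligomycin`, `fccp`, `rotenone`, `antimycin_a`) and `protein_ug`.
#' @return object of class `ocr_summary`: list with `basal`,
#'   `oligo_sensitive`, `nonmito`, `protein_ug` (basal and
#'   oligo_sensitive per unit protein).
#' @export
ocr_summary <- function(series) {
  inj <- series_attr(series, "injections_s")
  need <- c("oligomycin", "fccp", "rotenone", "antimycin_a")
  if (!all(need %in% names(inj)))
    stop("injections_s must name ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(diff(inj[need]) <= 0))
    stop("injections must be ordered oligomycin -> FCCP -> rotenone -> ",
         "antimycin A", call. = FALSE)
  protein <- attr(series, "protein_ug", exact = TRUE)
  if (is.null(protein)) protein <- 1
  t <- series$time_s; y <- series$ocr
  plateau <- function(lo, hi) {
    v <- y[t >= lo & t < hi]
    if (length(v) < 1L) stop("no samples in plateau [", lo, ", ", hi, ") s",
                             call. = FALSE)
    mean(utils::tail(v, 3L))
  }
  post_aa <- y[t > inj[["antimycin_a"]]]
  if (length(post_aa) < 3L)
    stop("missing rotenone/antimycin plateau: need at least 3 samples ",
         "after the antimycin A injection", call. = FALSE)
  nonmito <- mean(utils::tail(post_aa, 3L))
  basal_raw <- plateau(0, inj[["oligomycin"]])
  post_oligo <- plateau(inj[["oligomycin"]], inj[["fccp"]])
  structure(list(basal = (basal_raw - nonmito) / protein,
                 oligo_sensitive = (basal_raw - post_oligo) / protein,
                 nonmito = nonmito / protein,
                 protein_ug = protein),
            class = "ocr_summary")
}

#' @export
print.ocr_summary <- function(x, ...) {
  cat("<ocr_summary> basal ", round(x$basal, 2), ", oligomycin-sensitive ",
      round(x$oligo_sensitive, 2), " (nonmito ", round(x$nonmito, 2),
      ") per ", x$protein_ug, " ug protein\n", sep = "")
  invisible(x)
}

#' Summarize ROI fluorescence timecourses
#'
#' Per ROI: subtracts the camera background and normalizes each channel
#' to its pre-addition mean (or first frame). Per condition: mean +/- SEM
#' trace across ROIs (SEM over the ROI count, matching how figure legends
#' count n) and a scalar readout, the normalized intensity
#' `readout_offset_s` (default 480 s = 8 min) after the addition.
#' When several conditions are supplied, conditions are compared pairwise
#' on their per-ROI readouts with [group_compare()].
#'
#' @param sets a `roi_timecourse_set` or list of them (one per condition;
#'   each carries its `condition` attribute).
#' @param readout_offset_s readout time after addition, s.
#' @param normalize `"pre_mean"` (default) or `"first_frame"`.
#' @return object of class `timecourse_summary`: list with `traces`
#'   (data.frame `condition`, `time_s`, channel means and SEMs, `n_rois`),
#'   `readouts` (per condition x channel: mean, sem, n), `roi_readouts`,
#'   and `comparisons` (data.frame of pairwise t-tests, or `NULL`).
#' @export
summarize_timecourse <- function(sets, readout_offset_s = 480,
                                 normalize = c("pre_mean", "first_frame")) {
  normalize <- match.arg(normalize)
  if (inherits(sets, "roi_timecourse_set")) sets <- list(sets)
  per_roi <- list(); traces <- list()
  for (set in sets) {
    cond <- series_attr(set, "condition")
    add_t <- series_attr(set, "addition_time_s")
    bg <- series_attr(set, "background")
    rois <- split(set, set$roi)
    if (length(rois) < 2L)
      stop("need at least 2 ROIs per condition", call. = FALSE)
    t_grid <- sort(unique(set$time_s))
    readout_t <- add_t + readout_offset_s
    norm_one <- function(d, chan) {
      y <- d[[chan]] - bg[[chan]]
      ref <- if (normalize == "pre_mean") {
        pre <- y[d$time_s < add_t]
        if (!length(pre)) stop("no pre-addition samples to normalize to",
                               call. = FALSE)
        mean(pre)
      } else y[1]
      y / ref
    }
    cal <- vapply(rois, norm_one, numeric(length(t_grid)), chan = "calcein")
    tmr <- vapply(rois, norm_one, numeric(length(t_grid)), chan = "tmrm")
    sem <- function(m) apply(m, 1, stats::sd) / sqrt(ncol(m))
    traces[[cond]] <- data.frame(
      condition = cond, time_s = t_grid,
      calcein_mean = rowMeans(cal), calcein_sem = sem(cal),
      tmrm_mean = rowMeans(tmr), tmrm_sem = sem(tmr),
      n_rois = ncol(cal))
    at_readout <- function(m) apply(m, 2, function(y)
      stats::approx(t_grid, y, xout = readout_t, rule = 2)$y)
    per_roi[[cond]] <- data.frame(condition = cond,
                                  roi = as.integer(names(rois)),
                                  calcein = at_readout(cal),
                                  tmrm = at_readout(tmr))
  }
  roi_readouts <- do.call(rbind, per_roi)
  readouts <- do.call(rbind, lapply(split(roi_readouts, roi_readouts$condition),
    function(d) data.frame(
      condition = d$condition[1],
      channel = c("calcein", "tmrm"),
      mean = c(mean(d$calcein), mean(d$tmrm)),
      sem = c(stats::sd(d$calcein), stats::sd(d$tmrm)) / sqrt(nrow(d)),
      n_rois = nrow(d))))
  rownames(readouts) <- NULL
  comparisons <- NULL
  conds <- names(per_roi)
  if (length(conds) > 1L) {
    pairs <- utils::combn(conds, 2, simplify = FALSE)
    comparisons <- do.call(rbind, lapply(pairs, function(p) {
      do.call(rbind, lapply(c("calcein", "tmrm"), function(ch) {
        tt <- group_compare(per_roi[[p[1]]][[ch]], per_roi[[p[2]]][[ch]])
        data.frame(condition_a = p[1], condition_b = p[2], channel = ch,
                   statistic = tt$statistic, df = tt$df,
                   p_value = tt$p_value)
      }))
    }))
  }
  structure(list(traces = do.call(rbind, traces), readouts = readouts,
                 roi_readouts = roi_readouts, comparisons = comparisons,
                 readout_offset_s = readout_offset_s,
                 normalize = normalize),
            class = "timecourse_summary")
}

#' @export
print.timecourse_summary <- function(x, ...) {
  cat("<timecourse_summary> readout ", x$readout_offset_s,
      " s after addition (normalized to ", x$normalize, ")\n", sep = "")
  print(transform(x$readouts, mean = round(mean, 3), sem = round(sem, 3)))
  if (!is.null(x$comparisons)) {
    cat("  pairwise comparisons:\n")
    print(transform(x$comparisons, statistic = round(statistic, 2),
                    p_value = signif(p_value, 3)))
  }
  invisible(x)
}

#' Ratiometric GCaMP signal
#'
#' Background-corrected excitation ratio
#' `R(t) = (F475 - bg475) / (F410 - bg410)`. Points whose denominator is
#' not positive after background subtraction are masked (`NA`) with a
#' warning.
#'
#' @param f475,f410 fluorescence series at 475 and 410 nm excitation
#'   (equal length).
#' @param bg475,bg410 backgrounds.
#' @return numeric ratio series.
#' @export
gcamp_ratio <- function(f475, f410, bg475 = 0, bg410 = 0) {
  if (length(f475) != length(f410))
    stop("f475 and f410 must have equal length", call. = FALSE)
  num <- f475 - bg475
  den <- f410 - bg410
  bad <- den <= 0
  if (any(bad)) {
    warning(sum(bad), " point(s) masked: denominator <= 0 after ",
            "background subtraction")
    den[bad] <- NA_real_
  }
  num / den
}
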