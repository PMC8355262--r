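TRACE_KEYS <- c("holding_potential_mV", "sampling_rate_hz",
                "filter_cutoff_hz")

#' Write / read a current trace file
#'
#' The native trace dialect is plain text: a header block of `# key: value`
#' lines carrying the recording protocol (`holding_potential_mV`,
#' `sampling_rate_hz`, `filter_cutoff_hz`, and `interventions` as
#' comma-separated `label@time_s` tokens), followed by a CSV body with
#' columns `time_s,current_pA`. The round trip is lossless to well below
#' 1e-9 pA. Interventions read back carry label and time only (rate
#' multipliers are simulator-side quantities).
#'
#' @param trace a `ptp_trace`.
#' @param path file path.
#' @return `write_trace` returns `path` invisibly; `read_trace` returns a
#'   `ptp_trace`.
#' @export
write_trace <- function(trace, path) {
  p <- trace$protocol
  iv <- vapply(trace$interventions,
               function(i) paste0(i$label, "@", format(i$time_s)), "")
  header <- c(
    paste0("# holding_potential_mV: ", format(p$holding_potential_mV)),
    paste0("# sampling_rate_hz: ", format(p$sampling_rate_hz)),
    paste0("# filter_cutoff_hz: ", format(p$filter_cutoff_hz)),
    paste0("# interventions: ", paste(iv, collapse = ",")))
  writeLines(header, path)
  dt <- data.table::data.table(time_s = trace_times(trace),
                               current_pA = trace$current_pA)
  data.table::fwrite(dt, path, append = TRUE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  lines <- readLines(path, n = 100L)
  hdr_n <- which(!startsWith(lines, "#"))[1] - 1L
  if (is.na(hdr_n)) stop("no data section found in ", path, call. = FALSE)
  keys <- list()
  for (i in seq_len(hdr_n)) {
    m <- regmatches(lines[i], regexec("^#\\s*([A-Za-z0-9_]+)\\s*:\\s*(.*)$",
                                      lines[i]))[[1]]
    if (length(m) != 3L)
      stop("malformed header at line ", i, " of ", path, ": \"", lines[i],
           "\"", call. = FALSE)
    keys[[m[2]]] <- trimws(m[3])
  }
  for (k in TRACE_KEYS)
    if (is.null(keys[[k]]))
      stop("trace file ", path, " is missing mandatory header key `", k,
           "` (header lines 1-", hdr_n, ")", call. = FALSE)
  dt <- data.table::fread(path, skip = hdr_n, header = TRUE)
  if (!all(c("time_s", "current_pA") %in% names(dt)))
    stop("trace body must have columns time_s,current_pA", call. = FALSE)
  tm <- dt$time_s
  if (any(diff(tm) <= 0))
    stop("non-monotone time column in ", path, " near line ",
         hdr_n + 1L + which(diff(tm) <= 0)[1], call. = FALSE)
  fs <- as.numeric(keys$sampling_rate_hz)
  proto <- recording_protocol(
    holding_potential_mV = as.numeric(keys$holding_potential_mV),
    sampling_rate_hz = fs,
    filter_cutoff_hz = as.numeric(keys$filter_cutoff_hz),
    duration_s = length(tm) / fs)
  ivs <- parse_interventions(keys$interventions)
  new_trace(proto, dt$current_pA, ivs)
}

parse_interventions <- function(text) {
  if (is.null(text) || !nzchar(text)) return(list())
  toks <- strsplit(text, ",", fixed = TRUE)[[1]]
  lapply(toks, function(tok) {
    m <- regmatches(tok, regexec("^(.+)@([0-9.eE+-]+)$", tok))[[1]]
    if (length(m) != 3L)
      stop("malformed intervention token \"", tok,
           "\" (expected label@time_s)", call. = FALSE)
    intervention(as.numeric(m[3]), m[2])
  })
}

#' Write / read an assay series file
#'
#' Assay tables use the same dialect as traces: `# key: value` header
#' lines followed by a CSV body. The `type` key selects the series class
#' on reading (`absorbance`, `fluorescence`, `ocr`, `timecourse`); the
#' remaining header keys restore the series attributes (event timestamps,
#' protein content, backgrounds, condition).
#'
#' @param series an assay series produced by the `simulate_*` functions
#'   or assembled with matching attributes.
#' @param path file path.
#' @return `write_series` returns `path` invisibly; `read_series` returns
#'   the series with its class and attributes restored.
#' @export
write_series <- function(series, path) {
  hdr <- character(0)
  put <- function(key, val) paste0("# ", key, ": ",
                                   paste(vapply(unname(val), format, "",
                                                digits = 15),
                                         collapse = ","))
  if (inherits(series, "absorbance_series")) {
    hdr <- c(put("type", "absorbance"),
             put("ca_time_s", attr(series, "ca_time_s")),
             put("ala_time_s", attr(series, "ala_time_s")))
  } else if (inherits(series, "fluorescence_series")) {
    hdr <- c(put("type", "fluorescence"),
             put("pulse_times_s", attr(series, "pulse_times_s")))
  } else if (inherits(series, "ocr_series")) {
    inj <- attr(series, "injections_s")
    hdr <- c(put("type", "ocr"),
             put("injections_s", inj),
             put("injection_labels", names(inj)),
             put("protein_ug", attr(series, "protein_ug")))
  } else if (inherits(series, "roi_timecourse_set")) {
    bg <- attr(series, "background")
    hdr <- c(put("type", "timecourse"),
             put("addition_time_s", attr(series, "addition_time_s")),
             put("background_calcein", bg[["calcein"]]),
             put("background_tmrm", bg[["tmrm"]]),
             put("condition", attr(series, "condition")))
  } else stop("unsupported series class: ", paste(class(series),
                                                  collapse = "/"),
              call. = FALSE)
  writeLines(hdr, path)
  data.table::fwrite(as.data.frame(series)[], path, append = TRUE,
                     col.names = TRUE)
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path) {
  lines <- readLines(path, n = 50L)
  hdr_n <- which(!startsWith(lines, "#"))[1] - 1L
  keys <- list()
  for (i in seq_len(hdr_n)) {
    m <- regmatches(lines[i], regexec("^#\\s*([A-Za-z0-9_]+)\\s*:\\s*(.*)$",
                                      lines[i]))[[1]]
    if (length(m) != 3L)
      stop("malformed header at line ", i, " of ", path, call. = FALSE)
    keys[[m[2]]] <- trimws(m[3])
  }
  if (is.null(keys$type))
    stop("series file ", path, " is missing the `type` header key",
         call. = FALSE)
  body <- as.data.frame(data.table::fread(path, skip = hdr_n, header = TRUE))
  nums <- function(key) as.numeric(strsplit(keys[[key]], ",")[[1]])
  switch(keys$type,
    absorbance = structure(body, ca_time_s = nums("ca_time_s"),
                           ala_time_s = nums("ala_time_s"),
                           class = c("absorbance_series", "data.frame")),
    fluorescence = structure(body, pulse_times_s = nums("pulse_times_s"),
                             class = c("fluorescence_series", "data.frame")),
    ocr = {
      inj <- nums("injections_s")
      names(inj) <- strsplit(keys$injection_labels, ",")[[1]]
      structure(body, injections_s = inj, protein_ug = nums("protein_ug"),
                class = c("ocr_series", "data.frame"))
    },
    timecourse = structure(
      body, addition_time_s = nums("addition_time_s"),
      background = c(calcein = nums("background_calcein"),
                     tmrm = nums("background_tmrm")),
      condition = keys$condition,
      class = c("roi_timecourse_set", "data.frame")),
    stop("unknown series type \"", keys$type, "\" in ", path, call. = FALSE))
}

#' Write / read a run configuration
#'
#' Run configurations (analysis parameters, simulation presets and seeds,
#' output directory, log level) serialize to YAML so that every run can
#' store its resolved configuration beside its outputs and be reproduced
#' from it.
#'
#' @param config a named list; analysis parameters live under `analysis`
#'   and are validated through [analysis_config()] on reading.
#' @param path file path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   returns the configuration list with `analysis` as an
#'   [analysis_config()].
#' @export
write_run_config <- function(config, path) {
  cfg <- config
  if (inherits(cfg$analysis, "analysis_config"))
    cfg$analysis <- unclass(cfg$analysis)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$analysis))
    cfg$analysis <- do.call(analysis_config, cfg$analysis)
  cfg
}

#' Write idealization and event tables
#'
#' Emits the idealization as a delimited table (`start_s`, `end_s`,
#' `level_id`, `conductance_pS`) and the transition events as
#' (`time_s`, `duration_ms`, `from`, `to`, `delta_g_pS`).
#'
#' @param ideal a [idealize()] result.
#' @param levels the matching [extract_levels()] result.
#' @param events a [detect_transitions()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_idealization <- function(ideal, levels, path) {
  seg <- ideal$segments
  out <- data.frame(start_s = seg$start_s, end_s = seg$end_s,
                    level_id = seg$level,
                    conductance_pS = levels$levels$conductance_pS[
                      match(seg$level, levels$levels$level)])
  data.table::fwrite(out, path)
  invisible(path)
}

#' @rdname write_idealization
#' @export
write_events <- function(events, path) {
  out <- data.frame(time_s = events$time_s, duration_ms = events$duration_ms,
                    from = events$from_level, to = events$to_level,
                    delta_g_pS = events$delta_g_pS)
  data.table::fwrite(out, path)
  invisible(path)
}
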