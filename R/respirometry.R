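#' Open-flow respirometry trace
#'
#' Container for a raw heliox respirometry recording: a ~1 Hz time series of
#' excurrent O2 fraction and flow rate, together with the nominal incurrent
#' fraction and the index ranges during which the chamber held no animal
#' (baseline segments).  Baseline segments bracket the animal segment and are
#' the anchor points for drift correction.
#'
#' @param time_s numeric, seconds, strictly increasing.
#' @param feo2 numeric, fractional excurrent O2 (0 to fio2 + tolerance).
#' @param flow numeric scalar or per-sample vector, ml min^-1 (STP-corrected).
#' @param fio2 nominal incurrent O2 fraction (0.2095 for 21% O2 / 79% He).
#' @param baselines data.frame with columns `start`, `end` (1-based sample
#'   indices, inclusive) and `phase` ("pre" or "post").
#' @return A `resp_trace`: a data.frame (`time_s`, `feo2`, `flow`) with the
#'   baseline table and `fio2` stored as attributes.
#' @export
resp_trace <- function(time_s, feo2, flow, fio2 = 0.2095, baselines) {
  n <- length(time_s)
  if (n < 2 || any(diff(time_s) <= 0))
    stop_tf("time_s must be strictly increasing with >= 2 samples")
  if (length(feo2) != n) stop_tf("feo2 length must match time_s")
  flow <- rep_len(flow, n)
  if (any(flow <= 0)) stop_tf("flow must be positive")
  if (any(feo2 <= 0) || any(feo2 > fio2 + 0.01))
    stop_tf("feo2 outside (0, fio2 + tolerance)")
  stopifnot(is.data.frame(baselines),
            all(c("start", "end", "phase") %in% names(baselines)))
  if (any(baselines$start < 1) || any(baselines$end > n) ||
      any(baselines$start > baselines$end))
    stop_tf("baseline segment indices out of range")
  out <- data.frame(time_s = time_s, feo2 = feo2, flow = flow)
  attr(out, "fio2") <- fio2
  attr(out, "baselines") <- baselines
  class(out) <- c("resp_trace", "data.frame")
  out
}

baseline_idx <- function(trace, phase) {
  b <- attr(trace, "baselines")
  b <- b[b$phase == phase, , drop = FALSE]
  if (!nrow(b)) return(integer(0))
  unlist(lapply(seq_len(nrow(b)), function(i) b$start[i]:b$end[i]))
}

animal_idx <- function(trace) {
  b <- attr(trace, "baselines")
  base <- unlist(lapply(seq_len(nrow(b)), function(i) b$start[i]:b$end[i]))
  setdiff(seq_len(nrow(trace)), base)
}

#' Correct baseline drift in a respirometry trace
#'
#' Replaces the nominal incurrent O2 fraction with a time-varying reference:
#' the linear interpolation, in time, between the mean excurrent fraction of
#' the pre-animal baseline segments and that of the post-animal segments
#' (anchored at each phase's mean timestamp, extended linearly beyond the
#' anchors).  Animal-segment depletion is subsequently measured against this
#' reference, so a slow sensor or supply drift common to baselines and animal
#' readings cancels.  A missing pre or post baseline is a QC failure, not an
#' error: the trace is returned with `qc_fail` set.
#'
#' @param trace a [resp_trace()].
#' @return The trace with a `ref_o2` column and attributes `baseline_drift`
#'   (absolute difference of post- and pre-baseline means, O2 fraction) and,
#'   on failure, `qc_fail` (character reason).
#' @export
correct_baseline_drift <- function(trace) {
  pre <- baseline_idx(trace, "pre")
  post <- baseline_idx(trace, "post")
  if (!length(pre) || !length(post)) {
    attr(trace, "qc_fail") <- "baseline_missing"
    attr(trace, "baseline_drift") <- NA_real_
    return(trace)
  }
  m_pre <- mean(trace$feo2[pre]);  t_pre <- mean(trace$time_s[pre])
  m_post <- mean(trace$feo2[post]); t_post <- mean(trace$time_s[post])
  slope <- if (t_post > t_pre) (m_post - m_pre) / (t_post - t_pre) else 0
  trace$ref_o2 <- m_pre + slope * (trace$time_s - t_pre)
  attr(trace, "baseline_drift") <- abs(m_post - m_pre)
  trace
}

#' Per-sample oxygen consumption from a drift-corrected trace
#'
#' Computes VO2 for the animal segment using the steady-state equation for a
#' dry, CO2-scrubbed excurrent stream with flow measured downstream:
#' `VO2 = flow * (FiO2(t) - FeO2(t)) / (1 - FiO2(t))` in ml O2 min^-1, where
#' `FiO2(t)` is the drift-corrected reference.  Samples in which the
#' excurrent fraction exceeds the reference beyond `tol` are physically
#' impossible (sensor glitch), flagged `NA`, and excluded from windows
#' downstream.  An optional first-order washout correction is available when
#' the effective chamber volume is known: the excurrent fraction is advanced
#' by `(V/flow) * dFeO2/dt` before applying the equation.
#'
#' @param trace a drift-corrected [resp_trace()] (see
#'   [correct_baseline_drift()]).
#' @param tol tolerance (O2 fraction) above the reference before a sample is
#'   flagged.
#' @param effective_volume optional effective chamber volume (ml) enabling
#'   the washout ("instantaneous") correction; `NULL` disables it.
#' @return data.frame `time_s`, `vo2` (ml O2 min^-1, `NA` for flagged
#'   samples) restricted to the animal segment, with attribute `flow_cv`
#'   (coefficient of variation of flow over the animal segment) and
#'   `n_flagged`.
#' @export
compute_vo2 <- function(trace, tol = 5e-4, effective_volume = NULL) {
  if (is.null(trace$ref_o2))
    stop_tf("trace has no ref_o2; run correct_baseline_drift() first")
  idx <- animal_idx(trace)
  tt <- trace$time_s[idx]
  fe <- trace$feo2[idx]
  fl <- trace$flow[idx]
  if (!is.null(effective_volume)) {
    dfe <- c(diff(fe) / diff(tt), 0)
    dfe[length(dfe)] <- dfe[length(dfe) - 1]
    fe <- fe + (effective_volume / fl) * dfe * 60  # flow is per minute
  }
  ref <- trace$ref_o2[idx]
  vo2 <- fl * (ref - fe) / (1 - ref)
  bad <- fe > ref + tol
  vo2[bad] <- NA_real_
  out <- data.frame(time_s = tt, vo2 = vo2)
  attr(out, "flow_cv") <- if (mean(fl) > 0) sd(fl) / mean(fl) else NA_real_
  attr(out, "baseline_drift") <- attr(trace, "baseline_drift")
  attr(out, "n_flagged") <- sum(bad)
  out
}

#' Extract summit metabolism from a VO2 series
#'
#' M_sum is the highest VO2 averaged over any contiguous window of
#' `window_s` seconds (5 min by default).  Window means are computed on
#' samples (the sampling interval is taken as the median time step); windows
#' containing flagged (`NA`) samples are skipped; ties between equal-mean
#' windows are broken by the earliest start.
#'
#' @param vo2 data.frame from [compute_vo2()], or any data.frame with
#'   `time_s` and `vo2` columns.
#' @param window_s averaging period in seconds.
#' @return A `metabolic_summary` list: `msum`, `window_start`, `window_end`
#'   (seconds), `baseline_drift`, `flow_cv`, `qc_pass` (`NA` until
#'   [qc_trace()] is applied) and `qc_reasons`.
#' @export
extract_msum <- function(vo2, window_s = 300) {
  dt <- median(diff(vo2$time_s))
  wn <- max(1L, as.integer(round(window_s / dt)))
  n <- nrow(vo2)
  out <- list(msum = NA_real_, window_start = NA_real_, window_end = NA_real_,
              baseline_drift = attr(vo2, "baseline_drift") %||% NA_real_,
              flow_cv = attr(vo2, "flow_cv") %||% NA_real_,
              window_s = window_s, qc_pass = NA, qc_reasons = character(0))
  class(out) <- "metabolic_summary"
  if (n < wn) {
    out$qc_pass <- FALSE
    out$qc_reasons <- "duration"
    return(out)
  }
  x <- vo2$vo2
  cs <- cumsum(ifelse(is.na(x), 0, x))
  cna <- cumsum(is.na(x))
  starts <- seq_len(n - wn + 1L)
  sums <- cs[starts + wn - 1L] - c(0, cs)[starts]
  nas <- cna[starts + wn - 1L] - c(0, cna)[starts]
  means <- sums / wn
  means[nas > 0] <- NA_real_
  if (all(is.na(means))) {
    out$qc_pass <- FALSE
    out$qc_reasons <- "all_windows_flagged"
    return(out)
  }
  best <- which.max(means)  # earliest maximum on ties
  out$msum <- means[best]
  out$window_start <- vo2$time_s[best]
  out$window_end <- vo2$time_s[best + wn - 1L]
  out
}

#' Quality-control decision for a metabolic summary
#'
#' A measurement passes when the baseline drift does not exceed `drift_max`
#' and the flow coefficient of variation does not exceed `flow_cv_max`.
#' The thresholds are configuration parameters; the defaults (0.005 O2
#' fraction, 5% flow CV) are deliberately prominent and should be reviewed
#' for any new instrument setup.
#'
#' @param summary a `metabolic_summary` from [extract_msum()].
#' @param drift_max maximum tolerated absolute baseline drift (O2 fraction).
#' @param flow_cv_max maximum tolerated flow CV (fraction).
#' @return The summary with `qc_pass` and `qc_reasons` filled in
#'   ("baseline_drift", "flow", and/or any pre-existing failure reason).
#' @export
qc_trace <- function(summary, drift_max = 0.005, flow_cv_max = 0.05) {
  reasons <- summary$qc_reasons
  if (is.na(summary$baseline_drift)) {
    reasons <- union(reasons, "baseline_missing")
  } else if (summary$baseline_drift > drift_max) {
    reasons <- union(reasons, "baseline_drift")
  }
  if (!is.na(summary$flow_cv) && summary$flow_cv > flow_cv_max)
    reasons <- union(reasons, "flow")
  summary$qc_reasons <- reasons
  summary$qc_pass <- length(reasons) == 0 && !is.na(summary$msum)
  summary
}

#' @export
print.metabolic_summary <- function(x, ...) {
  cat("<metabolic_summary> M_sum =", round(x$msum, 4), "ml O2/min over [",
      x$window_start, ",", x$window_end, "] s; drift =",
      signif(x$baseline_drift, 3), "; flow CV =", signif(x$flow_cv, 3),
      "; qc_pass =", x$qc_pass,
      if (length(x$qc_reasons)) paste0("(", paste(x$qc_reasons, collapse = ","), ")")
      else "", "\n")
  invisible(x)
}

#' Process one trace end to end
#'
#' Convenience wrapper: drift correction, VO2 computation, sliding-window
#' M_sum extraction and QC in one call.
#'
#' @inheritParams compute_vo2
#' @inheritParams extract_msum
#' @inheritParams qc_trace
#' @param trace a [resp_trace()].
#' @return A `metabolic_summary`.
#' @export
process_trace <- function(trace, window_s = 300, drift_max = 0.005,
                          flow_cv_max = 0.05, effective_volume = NULL) {
  trace <- correct_baseline_drift(trace)
  if (!is.null(attr(trace, "qc_fail"))) {
    out <- list(msum = NA_real_, window_start = NA_real_,
                window_end = NA_real_, baseline_drift = NA_real_,
                flow_cv = NA_real_, window_s = window_s,
                qc_pass = FALSE, qc_reasons = attr(trace, "qc_fail"))
    class(out) <- "metabolic_summary"
    return(out)
  }
  vo2 <- compute_vo2(trace, effective_volume = effective_volume)
  qc_trace(extract_msum(vo2, window_s = window_s),
           drift_max = drift_max, flow_cv_max = flow_cv_max)
}

#' Read and write respirometry traces as delimited files
#'
#' A trace is stored as a CSV (`time_s`, `feo2`, `flow_ml_min`) plus a JSON
#' sidecar holding `fio2` and the baseline segment table.
#'
#' @param trace a [resp_trace()].
#' @param path path of the CSV file; the sidecar uses the same path with a
#'   `.json` extension appended.
#' @return `write_trace` invisibly returns the CSV path; `read_trace`
#'   returns a [resp_trace()].
#' @export
write_trace <- function(trace, path) {
  df <- data.frame(time_s = trace$time_s, feo2 = trace$feo2,
                   flow_ml_min = trace$flow)
  write.csv(df, path, row.names = FALSE)
  side <- list(fio2 = attr(trace, "fio2"),
               baselines = attr(trace, "baselines"))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- read.csv(path)
  side <- jsonlite::fromJSON(paste0(path, ".json"))
  resp_trace(df$time_s, df$feo2, df$flow_ml_min, fio2 = side$fio2,
             baselines = as.data.frame(side$baselines))
}

#' Process a directory of trace files into an M_sum table
#'
#' @param dir directory containing `*.csv` traces written by
#'   [write_trace()].
#' @inheritParams process_trace
#' @return data.frame with one row per trace: `id` (file stem), `msum`,
#'   `window_start`, `window_end`, `baseline_drift`, `flow_cv`, `qc_pass`,
#'   `qc_reasons`.
#' @export
process_trace_dir <- function(dir, window_s = 300, drift_max = 0.005,
                              flow_cv_max = 0.05) {
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  rows <- lapply(files, function(f) {
    s <- process_trace(read_trace(f), window_s = window_s,
                       drift_max = drift_max, flow_cv_max = flow_cv_max)
    data.frame(id = sub("\\.csv$", "", basename(f)), msum = s$msum,
               window_start = s$window_start, window_end = s$window_end,
               baseline_drift = s$baseline_drift, flow_cv = s$flow_cv,
               qc_pass = s$qc_pass,
               qc_reasons = paste(s$qc_reasons, collapse = ";"))
  })
  do.call(rbind, rows)
}
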