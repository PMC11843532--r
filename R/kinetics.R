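#' Detect the onset of a rising signal
#'
#' Operationalizes "the signal starts to increase at time t": the onset is
#' the first time the series exceeds
#' `baseline_mean + max(k * baseline_sd, min_rise * (max(series) - baseline_mean))`
#' for `m` consecutive samples, linearly interpolated to the threshold
#' crossing. The baseline is the first `baseline_n` samples; its SD is
#' computed after removing a linear trend so that a drifting baseline
#' measures noise, not drift. The dynamic-range floor `min_rise` keeps the
#' onset well defined on noiseless traces (where the baseline SD is zero and
#' any infinitesimal rise would otherwise trigger); both the rule and its
#' parameters are reported in pipeline output. The rule is equivariant under
#' time shifts and invariant under positive affine scaling of the series.
#'
#' @param series Numeric signal values.
#' @param times_h Times (hours), same length, strictly increasing.
#' @param baseline_n Number of initial samples defining the baseline (>= 3).
#' @param k Threshold multiplier on the baseline SD (default 3).
#' @param m Consecutive samples required above threshold (default 2).
#' @param min_rise Dynamic-range floor as a fraction of the series' total
#'   rise above baseline (default 0.05).
#' @return Onset time in hours, or `NA_real_` if the series never sustains a
#'   crossing.
#' @export
detect_onset <- function(series, times_h, baseline_n = 3L, k = 3, m = 2L,
                         min_rise = 0.05) {
  stopifnot(length(series) == length(times_h), baseline_n >= 3,
            length(series) > baseline_n + m)
  if (is.unsorted(times_h, strictly = TRUE)) {
    stop("`times_h` must be strictly increasing", call. = FALSE)
  }
  base <- series[seq_len(baseline_n)]
  rise <- max(series) - mean(base)
  if (rise <= 0) return(NA_real_)
  # baseline noise is the SD of the detrended baseline, so a drifting
  # baseline does not inflate the threshold
  bt <- times_h[seq_len(baseline_n)]
  base_sd <- stats::sd(stats::residuals(stats::lm(base ~ bt)))
  thr <- mean(base) + max(k * base_sd, min_rise * rise)
  above <- series > thr
  idx <- NA_integer_
  run <- 0L
  for (i in seq_along(above)) {
    run <- if (above[i]) run + 1L else 0L
    if (run == m) { idx <- i - m + 1L; break }
  }
  if (is.na(idx)) return(NA_real_)
  if (idx == 1L) return(times_h[1])
  # interpolate between the last sub-threshold sample and the crossing
  x0 <- series[idx - 1L]; x1 <- series[idx]
  t0 <- times_h[idx - 1L]; t1 <- times_h[idx]
  if (x1 == x0) return(t1)
  t0 + (thr - x0) / (x1 - x0) * (t1 - t0)
}

#' Half-rise time of a sigmoidal signal
#'
#' The t50 is the first time the series crosses
#' `baseline + 0.5 * (plateau - baseline)`, linearly interpolated, where the
#' baseline and plateau are the means of the first and last `edge_frac`
#' fraction of samples. Robust to non-logistic shapes; no curve fitting is
#' involved.
#'
#' @inheritParams detect_onset
#' @param edge_frac Fraction of samples (at least one sample) used for the
#'   baseline and plateau estimates (default 0.1).
#' @return The t50 in hours.
#' @export
t50 <- function(series, times_h, edge_frac = 0.1) {
  stopifnot(length(series) == length(times_h), length(series) >= 4)
  if (is.unsorted(times_h, strictly = TRUE)) {
    stop("`times_h` must be strictly increasing", call. = FALSE)
  }
  n_edge <- max(1L, floor(edge_frac * length(series)))
  baseline <- mean(series[seq_len(n_edge)])
  plateau <- mean(series[seq.int(length(series) - n_edge + 1L,
                                 length(series))])
  if (plateau <= baseline) {
    stop("no transition: plateau does not exceed baseline", call. = FALSE)
  }
  half <- baseline + 0.5 * (plateau - baseline)
  above <- which(series >= half)
  if (length(above) == 0L) {
    stop("series never reaches half-rise within the window", call. = FALSE)
  }
  i <- above[1]
  if (i == 1L) return(times_h[1])
  x0 <- series[i - 1L]; x1 <- series[i]
  if (x1 == x0) return(times_h[i])
  times_h[i - 1L] + (half - x0) / (x1 - x0) * (times_h[i] - times_h[i - 1L])
}

#' Kinetics summary of one aggregation trace
#'
#' Computes the lifetime-onset time, the intensity lag (onset of the
#' intensity channel), the intensity half-rise time t50, the final lifetime,
#' and the channel delay `intensity_t50_h - tau_m_onset_h`. The lifetime
#' channel of fibril-sensitive rotors rises before the intensity channel, so
#' the channel delay quantifies how much earlier pre-fibrillar species are
#' detected.
#'
#' @param trace An `aggregation_trace` (or any list with `time_h`, `tau_m`,
#'   `intensity`).
#' @param ... Passed on to [detect_onset()].
#' @return A one-row data.frame: `tau_m_onset_h`, `intensity_lag_h`,
#'   `intensity_t50_h`, `final_tau_m_ns`, `channel_delay_h`. Undefined
#'   quantities are `NA`.
#' @export
kinetics_summary <- function(trace, ...) {
  stopifnot(!is.null(trace$time_h), !is.null(trace$tau_m),
            !is.null(trace$intensity))
  onset <- detect_onset(trace$tau_m, trace$time_h, ...)
  lag <- detect_onset(trace$intensity, trace$time_h, ...)
  t50_i <- tryCatch(t50(trace$intensity, trace$time_h),
                    error = function(e) NA_real_)
  data.frame(
    tau_m_onset_h = onset,
    intensity_lag_h = lag,
    intensity_t50_h = t50_i,
    final_tau_m_ns = trace$tau_m[length(trace$tau_m)],
    channel_delay_h = t50_i - onset
  )
}

#' Compare aggregation kinetics across variants
#'
#' Summarizes each named trace with [kinetics_summary()] and reports deltas
#' of every variant against a designated reference variant (by default the
#' first), e.g. the extra delay a mutation imposes on the lifetime onset
#' versus on the intensity half-time.
#'
#' @param traces Named list of `aggregation_trace` objects (or compatible
#'   lists); all must carry `time_h`, `tau_m` and `intensity`.
#' @param reference Name of the reference variant (default: first name).
#' @param ... Passed on to [detect_onset()].
#' @return A data.frame with one row per variant: the [kinetics_summary()]
#'   columns plus `delta_tau_m_onset_h` and `delta_intensity_t50_h` relative
#'   to the reference.
#' @export
compare_variants <- function(traces, reference = names(traces)[1], ...) {
  if (!is.list(traces) || is.null(names(traces)) ||
      any(!nzchar(names(traces)))) {
    stop("`traces` must be a named list", call. = FALSE)
  }
  if (!reference %in% names(traces)) {
    stop("`reference` must name one of the traces", call. = FALSE)
  }
  for (tr in traces) {
    if (is.null(tr$time_h) || is.null(tr$tau_m) || is.null(tr$intensity)) {
      stop("every trace needs time_h, tau_m and intensity channels",
           call. = FALSE)
    }
  }
  rows <- lapply(names(traces), function(nm) {
    cbind(data.frame(variant = nm), kinetics_summary(traces[[nm]], ...))
  })
  out <- do.call(rbind, rows)
  ref <- out[out$variant == reference, ]
  out$delta_tau_m_onset_h <- out$tau_m_onset_h - ref$tau_m_onset_h
  out$delta_intensity_t50_h <- out$intensity_t50_h - ref$intensity_t50_h
  rownames(out) <- NULL
  out
}
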