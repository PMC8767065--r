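# Mitochondrial-potential (Rh123) recovery metrics: post-washout slope and
# the FCCP / post-glutamate AUC ratio.

#' Rh123 post-washout recovery slope
#'
#' Least-squares slope of F/F0 versus time over the washout window.
#' Negative slope = recovery (fluorescence decreasing back toward 1).
#'
#' @param trace an F/F0 [ratio_trace].
#' @param washout_window numeric length-2 `c(start, end)` seconds; defaults
#'   cannot be inferred here, use `[glu_off, fccp_on)` from the schedule.
#' @return list with `slope` (F/F0 per second), `intercept`, `rmse`, `n`.
#' @export
rh123_recovery_slope <- function(trace, washout_window) {
  stopifnot(length(washout_window) == 2L)
  idx <- trace$time >= washout_window[1] & trace$time < washout_window[2]
  if (sum(idx) < 3L)
    stop("washout window contains <3 samples", call. = FALSE)
  ols_fit(trace$time[idx], trace$values[idx])
}

#' Above-baseline area under the curve
#'
#' Trapezoidal integral of `max(signal - baseline_level, 0)` over a window,
#' on the trace's own sample grid. Exact for piecewise-linear signals whose
#' kinks lie on the grid.
#'
#' @param trace a [ratio_trace].
#' @param window numeric length-2 `c(start, end)` seconds, within the trace.
#' @param baseline_level level subtracted before integration; defaults to 1
#'   (the F/F0 pre-stimulus normalization level).
#' @return area in ratio-units x seconds (>= 0).
#' @export
signal_auc <- function(trace, window, baseline_level = 1) {
  stopifnot(length(window) == 2L)
  if (window[2] <= window[1]) stop("empty window", call. = FALSE)
  idx <- trace$time >= window[1] & trace$time <= window[2]
  if (sum(idx) < 2L) stop("window contains <2 samples", call. = FALSE)
  t <- trace$time[idx]
  v <- pmax(trace$values[idx] - baseline_level, 0)
  trapz(t, v)
}

#' FCCP / post-glutamate AUC ratio
#'
#' Ratio of the above-baseline Rh123 AUC during FCCP application to the AUC
#' in the post-glutamate period. A small ratio indicates little releasable
#' probe remained in mitochondria, i.e. sustained depolarization or probe
#' loss during washout. Undefined (NA) when the post-glutamate AUC is zero.
#'
#' @param trace an F/F0 [ratio_trace].
#' @param postglu_window,fccp_window numeric length-2 windows, disjoint and
#'   ordered (post-glutamate before FCCP).
#' @param baseline_level AUC baseline, default 1.
#' @return list with `ratio` (or `NA`), `defined`, `auc_postglu`,
#'   `auc_fccp`.
#' @export
auc_ratio <- function(trace, postglu_window, fccp_window,
                      baseline_level = 1) {
  if (postglu_window[2] > fccp_window[1] + 1e-9)
    stop("windows must be disjoint and ordered: post-glutamate before FCCP",
         call. = FALSE)
  a_post <- signal_auc(trace, postglu_window, baseline_level)
  a_fccp <- signal_auc(trace, fccp_window, baseline_level)
  if (a_post <= 0)
    return(list(ratio = NA_real_, defined = FALSE,
                auc_postglu = a_post, auc_fccp = a_fccp))
  list(ratio = a_fccp / a_post, defined = TRUE,
       auc_postglu = a_post, auc_fccp = a_fccp)
}

#' Analyze a cohort of Rh123 traces
#'
#' Computes the post-washout recovery slope and the FCCP/post-glutamate AUC
#' ratio for every cell. Windows are derived from the event schedule:
#' washout and post-glutamate window `[glu_off, fccp_on)`, FCCP window
#' `[fccp_on, iono_on)` (or trace end).
#'
#' @param cohort a `trace_cohort` of F/F0 traces (e.g. from
#'   [gen_mito_cohort()]).
#' @param events an [event_schedule]; defaults to the cohort's own.
#' @param baseline_level AUC baseline, default 1.
#' @return tibble with `cell_id`, `slope`, `slope_rmse`, `auc_postglu`,
#'   `auc_fccp`, `auc_ratio`, `auc_defined`.
#' @export
analyze_mito_cohort <- function(cohort, events = NULL, baseline_level = 1) {
  traces <- if (inherits(cohort, "trace_cohort")) cohort$traces else cohort
  events <- events %||%
    (if (inherits(cohort, "trace_cohort")) cohort$events else NULL)
  if (is.null(events)) stop("an event schedule is required", call. = FALSE)
  glu_off <- event_time(events, "glu_off")
  fccp_on <- event_time(events, "fccp_on")
  iono <- event_time(events, "iono_on", required = FALSE)
  rows <- lapply(traces, function(tr) {
    t_end <- if (!is.na(iono)) iono else max(tr$time)
    sl <- rh123_recovery_slope(tr, c(glu_off, fccp_on))
    ar <- auc_ratio(tr, c(glu_off, fccp_on), c(fccp_on, t_end),
                    baseline_level)
    tibble::tibble(cell_id = tr$cell_id, slope = sl$slope,
                   slope_rmse = sl$rmse, auc_postglu = ar$auc_postglu,
                   auc_fccp = ar$auc_fccp, auc_ratio = ar$ratio,
                   auc_defined = ar$defined)
  })
  do.call(rbind, rows)
}
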