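# Delayed calcium deregulation: classification, tangent-intersection lag,
# post-washout recovery index, sister-control normalization.

#' Classify a trace as DCD-positive or not
#'
#' A cell is DCD-positive when, after the first-phase plateau has settled,
#' the signal rises again above the plateau trend by more than
#' `threshold_k` robust (detrended) standard deviations — with a minimum
#' absolute rise of `min_rise_frac` times the first-phase amplitude — and
#' stays elevated until glutamate washout. The comparison uses the smoothed
#' signal against the plateau reference line, so drifting plateaus do not
#' trigger false positives. Ties at the threshold are negative (strict
#' inequality).
#'
#' @param trace a [ratio_trace].
#' @param events an [event_schedule] containing `glu_on` and `glu_off`.
#' @param threshold_k rise threshold in robust-sd units of the plateau.
#' @param min_rise_frac minimum rise as a fraction of the first-phase
#'   amplitude (plateau minus pre-glutamate baseline).
#' @param settle_s seconds after `glu_on` allowed for the first phase to
#'   settle before the plateau reference window starts.
#' @param plateau_ref_s width of the plateau reference window, seconds.
#' @param smooth_s smoothing width used for detection, seconds.
#' @param min_glu_window_s minimum glutamate-exposure duration, seconds.
#' @return list with `has_dcd`, `plateau_idx` (index range of the
#'   first-phase plateau), `rise_idx` (index range of the secondary rise, or
#'   `NULL`), `threshold`, `plateau_fit` (list slope/intercept) and
#'   `baseline` (pre-glutamate mean).
#' @export
classify_dcd <- function(trace, events, threshold_k = 5,
                         min_rise_frac = 0.1, settle_s = 20,
                         plateau_ref_s = 40, smooth_s = 15,
                         min_glu_window_s = 120) {
  glu_on <- event_time(events, "glu_on")
  glu_off <- event_time(events, "glu_off")
  if (glu_off - glu_on < min_glu_window_s)
    stop(sprintf("glutamate window shorter than the %g s minimum",
                 min_glu_window_s), call. = FALSE)
  t <- trace$time
  if (min(t) > glu_on || max(t) < glu_off)
    stop("trace does not cover the glutamate window", call. = FALSE)
  sm <- smooth_trace(trace, smooth_s)
  smv <- sm$values
  baseline <- mean(trace$values[t < glu_on])
  p_start <- glu_on + settle_s
  ref <- which(t >= p_start & t <= p_start + plateau_ref_s)
  if (length(ref) < 3L)
    stop("plateau reference window contains <3 samples", call. = FALSE)
  glu_idx <- which(t >= p_start & t <= glu_off)
  back_margin <- smooth_s + 2 * stats::median(diff(t))

  # The secondary rise must exceed the plateau *trend* and persist to
  # washout: the rise start is the beginning of the last above-threshold
  # run that extends to glu_off. A short reference window cannot anchor the
  # trend over a long plateau (slope errors extrapolate), so the plateau
  # line is re-estimated robustly (Theil-Sen) over everything up to the
  # provisional rise start and detection is repeated.
  detect <- function(fit, thr) {
    excess <- smv[glu_idx] - (fit$intercept + fit$slope * t[glu_idx])
    ok <- excess > thr
    if (!length(ok) || !ok[length(ok)]) return(NA_integer_)
    glu_idx[max(c(0L, which(!ok))) + 1L]
  }
  fit <- ols_fit(t[ref], smv[ref])[c("slope", "intercept")]
  resid <- smv[ref] - (fit$intercept + fit$slope * t[ref])
  level0 <- fit$intercept + fit$slope * p_start
  thr <- max(threshold_k * robust_sd(resid),
             min_rise_frac * (level0 - baseline), 0)
  rise_first <- detect(fit, thr)
  for (pass in 1:2) {
    upper <- if (is.na(rise_first)) glu_off else t[rise_first] - back_margin
    win <- glu_idx[t[glu_idx] <= upper]
    if (length(win) < max(8L, length(ref))) break
    fit <- theil_sen_fit(t[win], smv[win])
    resid <- smv[win] - (fit$intercept + fit$slope * t[win])
    level0 <- fit$intercept + fit$slope * p_start
    thr <- max(threshold_k * robust_sd(resid),
               min_rise_frac * (level0 - baseline), 0)
    rise_first <- detect(fit, thr)
  }

  has <- !is.na(rise_first)
  if (has) {
    pl_hi <- glu_idx[t[glu_idx] <= t[rise_first] - back_margin]
    pl_hi <- if (length(pl_hi)) max(pl_hi) else rise_first - 1L
    plateau_idx <- c(min(ref), max(min(ref) + 2L, pl_hi))
    rise_idx <- c(rise_first, max(glu_idx))
  } else {
    plateau_idx <- c(min(ref), max(glu_idx))
    rise_idx <- NULL
  }
  list(has_dcd = has, plateau_idx = plateau_idx, rise_idx = rise_idx,
       threshold = thr,
       plateau_fit = list(slope = fit$slope, intercept = fit$intercept),
       baseline = baseline)
}

#' Estimate the DCD lag by tangent intersection
#'
#' Fits a least-squares tangent to the first-phase plateau and a second
#' tangent to the maximal-slope segment of the secondary rise, and reports
#' the time from glutamate addition to the intersection of the two lines.
#' The intersection is clamped to the glutamate window (with a warning
#' flag) and an error is raised when the tangents are near-parallel.
#'
#' @param trace a [ratio_trace].
#' @param events an [event_schedule] with `glu_on` and `glu_off`.
#' @param phases phase boundaries from [classify_dcd()] (computed if
#'   missing).
#' @param secondary_window_s width of the maximal-slope fit window, seconds.
#'   The window must be narrow relative to the rise time of the secondary
#'   phase: a wide window fits a chord, not a tangent, and biases the
#'   intersection early.
#' @param slope_tol tangents with |slope difference| below this are
#'   considered parallel (degenerate geometry).
#' @param ... passed to [classify_dcd()] when `phases` is missing.
#' @return list with `lag_dcd` (seconds), `intersection_time`,
#'   `tangent_first` and `tangent_secondary` (each slope/intercept/rmse/
#'   window), and `clamped` flag.
#' @export
estimate_lag_dcd <- function(trace, events, phases = NULL,
                             secondary_window_s = 30, slope_tol = 1e-9,
                             ...) {
  if (is.null(phases)) phases <- classify_dcd(trace, events, ...)
  if (!isTRUE(phases$has_dcd))
    stop("estimate_lag_dcd requires a DCD-positive trace", call. = FALSE)
  glu_on <- event_time(events, "glu_on")
  glu_off <- event_time(events, "glu_off")
  t <- trace$time; v <- trace$values
  pi_ <- phases$plateau_idx
  fit1 <- ols_fit(t[pi_[1]:pi_[2]], v[pi_[1]:pi_[2]])
  ri <- phases$rise_idx
  rt <- t[ri[1]:ri[2]]; rv <- v[ri[1]:ri[2]]
  if (length(rt) < 3L)
    stop("secondary rise has <3 samples; cannot fit tangent", call. = FALSE)
  roll <- roll_ols_slope(rt, rv, secondary_window_s)
  if (all(is.na(roll$slope))) {
    win <- seq_along(rt)              # short rise: use the whole segment
  } else {
    i0 <- which.max(roll$slope)
    win <- i0:roll$end[i0]
  }
  fit2 <- ols_fit(rt[win], rv[win])
  if (abs(fit2$slope - fit1$slope) < slope_tol)
    stop("degenerate geometry: tangents are parallel", call. = FALSE)
  t_int <- (fit1$intercept - fit2$intercept) / (fit2$slope - fit1$slope)
  clamped <- t_int < glu_on || t_int > glu_off
  t_clamp <- min(max(t_int, glu_on), glu_off)
  if (clamped)
    warning("tangent intersection outside the glutamate window; clamped",
            call. = FALSE)
  list(
    lag_dcd = t_clamp - glu_on,
    intersection_time = t_clamp,
    tangent_first = c(fit1[c("slope", "intercept", "rmse")],
                      list(window = range(t[pi_[1]:pi_[2]]))),
    tangent_secondary = c(fit2[c("slope", "intercept", "rmse")],
                          list(window = range(rt[win]))),
    clamped = clamped)
}

#' Post-washout calcium recovery index (X, %)
#'
#' `X = 100 * (R_off - R_end) / (R_off - R_base)`, where `R_base` is the
#' pre-glutamate baseline mean, `R_off` the signal at glutamate washout and
#' `R_end` the signal at `glu_off + horizon`. 100% means full return to
#' baseline, 0% no recovery. The reported value is capped at 100; traces
#' with no elevation at washout (`R_off <= R_base`) are undefined and
#' flagged for exclusion. The index is a documented reconstruction of the
#' washout quantification: anchored at washout, fixed horizon, denominator
#' anchored at baseline.
#'
#' @param trace a [ratio_trace].
#' @param events an [event_schedule] with `glu_on`, `glu_off` and, for the
#'   default horizon, `fccp_on`.
#' @param horizon seconds after `glu_off` at which recovery is read out;
#'   default: the last sample before `fccp_on` (or the last sample).
#' @return list with `index` (percent or `NA`), `defined`, `r_base`,
#'   `r_off`, `r_end`, `horizon`.
#' @export
recovery_index <- function(trace, events, horizon = NULL) {
  glu_on <- event_time(events, "glu_on")
  glu_off <- event_time(events, "glu_off")
  t <- trace$time; v <- trace$values
  if (is.null(horizon)) {
    fccp <- event_time(events, "fccp_on", required = FALSE)
    t_end <- if (!is.na(fccp)) max(t[t < fccp]) else max(t)
    horizon <- t_end - glu_off
  }
  if (horizon <= 0) stop("recovery horizon must be positive", call. = FALSE)
  fccp <- event_time(events, "fccp_on", required = FALSE)
  if (!is.na(fccp) && glu_off + horizon > fccp + 1e-9)
    stop("recovery horizon reaches into the FCCP window", call. = FALSE)
  r_base <- mean(v[t < glu_on])
  r_off <- interp_at(t, v, glu_off)
  r_end <- interp_at(t, v, glu_off + horizon)
  if (r_off <= r_base)
    return(list(index = NA_real_, defined = FALSE, r_base = r_base,
                r_off = r_off, r_end = r_end, horizon = horizon))
  x <- 100 * (r_off - r_end) / (r_off - r_base)
  list(index = min(x, 100), defined = TRUE, r_base = r_base, r_off = r_off,
       r_end = r_end, horizon = horizon)
}

#' Normalize values to a sister-culture control
#'
#' Divides each value by the median of the paired control values, so the
#' control median maps to 1 (arbitrary units) exactly.
#'
#' @param values numeric vector (treated culture).
#' @param control_values numeric vector (sister control), non-empty.
#' @return numeric vector of normalized values.
#' @export
normalize_to_sister_control <- function(values, control_values) {
  control_values <- control_values[!is.na(control_values)]
  if (length(control_values) == 0)
    stop("control values are empty", call. = FALSE)
  med <- stats::median(control_values)
  if (med == 0) stop("control median is zero; cannot normalize", call. = FALSE)
  values / med
}

#' Analyze a full cohort of calcium traces
#'
#' Runs [classify_dcd()], [estimate_lag_dcd()] and [recovery_index()] on
#' every trace of a cohort and returns one row per cell.
#'
#' @param cohort a `trace_cohort` (or plain list of [ratio_trace]s plus an
#'   `events` argument).
#' @param events an [event_schedule]; defaults to the cohort's own.
#' @param ... tuning arguments passed to [classify_dcd()].
#' @return tibble with columns `cell_id`, `has_dcd`, `lag_dcd`,
#'   `recovery_index`, `recovery_defined`, `clamped`, `slope_first`,
#'   `slope_secondary`.
#' @export
analyze_dcd_cohort <- function(cohort, events = NULL, ...) {
  traces <- if (inherits(cohort, "trace_cohort")) cohort$traces else cohort
  events <- events %||%
    (if (inherits(cohort, "trace_cohort")) cohort$events else NULL)
  if (is.null(events)) stop("an event schedule is required", call. = FALSE)
  rows <- lapply(traces, function(tr) {
    cls <- classify_dcd(tr, events, ...)
    lag <- NA_real_; clamped <- NA; s1 <- NA_real_; s2 <- NA_real_
    if (cls$has_dcd) {
      est <- suppressWarnings(
        tryCatch(estimate_lag_dcd(tr, events, phases = cls),
                 error = function(e) NULL))
      if (!is.null(est)) {
        lag <- est$lag_dcd; clamped <- est$clamped
        s1 <- est$tangent_first$slope; s2 <- est$tangent_secondary$slope
      }
    }
    rec <- recovery_index(tr, events)
    tibble::tibble(cell_id = tr$cell_id, has_dcd = cls$has_dcd,
                   lag_dcd = lag, recovery_index = rec$index,
                   recovery_defined = rec$defined, clamped = clamped,
                   slope_first = s1, slope_secondary = s2)
  })
  do.call(rbind, rows)
}

#' Summarize a cohort of per-cell DCD results
#'
#' Medians and interquartile ranges are computed on defined values only;
#' counts of excluded cells are always reported.
#'
#' @param results tibble from [analyze_dcd_cohort()].
#' @return tibble with one row: `n`, `n_dcd`, `dcd_fraction`, `lag_median`,
#'   `lag_q1`, `lag_q3`, `recovery_median`, `recovery_q1`, `recovery_q3`,
#'   `n_recovery_excluded`, `n_lag_missing`.
#' @export
summarize_cohort <- function(results) {
  if (is.null(results) || nrow(results) == 0)
    stop("empty cohort", call. = FALSE)
  lag <- results$lag_dcd[results$has_dcd & !is.na(results$lag_dcd)]
  rec <- results$recovery_index[!is.na(results$recovery_index)]
  q <- function(x, p) if (length(x)) unname(stats::quantile(x, p, type = 7))
       else NA_real_
  tibble::tibble(
    n = nrow(results),
    n_dcd = sum(results$has_dcd),
    dcd_fraction = mean(results$has_dcd),
    lag_median = q(lag, 0.5), lag_q1 = q(lag, 0.25), lag_q3 = q(lag, 0.75),
    recovery_median = q(rec, 0.5), recovery_q1 = q(rec, 0.25),
    recovery_q3 = q(rec, 0.75),
    n_recovery_excluded = sum(!results$recovery_defined),
    n_lag_missing = sum(results$has_dcd & is.na(results$lag_dcd)))
}
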