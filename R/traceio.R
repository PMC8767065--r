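#' Read a table of per-cell fluorescence traces
#'
#' Accepts the two layouts commonly exported by imaging software:
#' long (`cell_id, time, value[, channel]`) or wide (first column time, one
#' column per cell). Times are coerced to seconds.
#'
#' @param path CSV file.
#' @param layout `"long"` or `"wide"`.
#' @param time_units `"s"` or `"min"`; minutes are converted to seconds.
#' @param channel channel label used for every trace when the table carries
#'   no `channel` column (wide layout always uses this).
#' @return a named list of [fluor_trace] objects (one per cell/channel;
#'   names are `cell_id` or `cell_id.channel` when several channels exist).
#' @export
read_trace_table <- function(path, layout = c("long", "wide"),
                             time_units = c("s", "min"), channel = "F") {
  layout <- match.arg(layout)
  time_units <- match.arg(time_units)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  k <- if (time_units == "min") 60 else 1
  if (layout == "wide") {
    if (ncol(df) < 2L) stop("wide table needs a time column plus >=1 cell column",
                            call. = FALSE)
    tm <- as.numeric(df[[1]]) * k
    check_time_column(tm, path)
    traces <- lapply(names(df)[-1], function(cn)
      fluor_trace(cn, tm, as.numeric(df[[cn]]), channel = channel))
    names(traces) <- names(df)[-1]
    return(traces)
  }
  need <- c("cell_id", "time", "value")
  names(df) <- sub("^time_s$", "time", names(df))
  if (!all(need %in% names(df)))
    stop("long table must have columns cell_id, time (or time_s), value",
         call. = FALSE)
  if (!"channel" %in% names(df)) df$channel <- channel
  df$time <- as.numeric(df$time) * k
  key <- interaction(df$cell_id, df$channel, drop = TRUE)
  if (anyDuplicated(paste(df$cell_id, df$channel, df$time)))
    stop("duplicate (cell, channel, time) rows in trace table", call. = FALSE)
  out <- lapply(split(df, key), function(d) {
    d <- d[order(d$time), , drop = FALSE]
    check_time_column(d$time, path)
    fluor_trace(d$cell_id[1], d$time, d$value, channel = d$channel[1])
  })
  out[order(names(out))]
}

check_time_column <- function(tm, path) {
  if (anyNA(tm)) stop(sprintf("non-numeric or missing times in %s", path),
                      call. = FALSE)
  if (any(diff(tm) <= 0))
    stop(sprintf("non-monotone time column in %s", path), call. = FALSE)
  invisible(TRUE)
}

#' Write traces to a long-format CSV
#'
#' Columns: `cell_id, time_s, value, channel`. Round-trips through
#' [read_trace_table()].
#'
#' @param traces a list of [fluor_trace]/[ratio_trace] objects.
#' @param path output CSV path.
#' @export
write_trace_table <- function(traces, path) {
  if (inherits(traces, "fluor_trace")) traces <- list(traces)
  df <- do.call(rbind, lapply(traces, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Two-excitation fluorescence ratio (F340/F380)
#'
#' Pointwise ratio of the two excitation channels of a ratiometric
#' indicator. Both traces must come from the same cell on an identical
#' time grid.
#'
#' @param f340,f380 [fluor_trace] objects for the numerator and denominator
#'   channels.
#' @return a [ratio_trace] of kind `"excitation_ratio"`.
#' @export
compute_excitation_ratio <- function(f340, f380) {
  if (!identical(f340$cell_id, f380$cell_id))
    stop("cell_id mismatch between channels", call. = FALSE)
  if (length(f340$time) != length(f380$time) ||
      any(abs(f340$time - f380$time) > 1e-9))
    stop("alignment error: the two channels are not on the same time grid",
         call. = FALSE)
  zero <- which(f380$values == 0)
  if (length(zero))
    stop(sprintf("zero denominator (F380) at sample index %d", zero[1]),
         call. = FALSE)
  ratio_trace(f340$cell_id, f340$time, f340$values / f380$values,
              kind = "excitation_ratio")
}

#' Normalize a trace to its initial (baseline) value
#'
#' Divides the signal by its mean over a baseline window preceding the first
#' stimulation, producing the F/F0 convention for single-channel probes.
#'
#' @param trace a [fluor_trace] or [ratio_trace].
#' @param baseline_window numeric length-2, `c(start, end)` in seconds.
#' @return a [ratio_trace] of kind `"f_over_f0"`.
#' @export
normalize_to_initial <- function(trace, baseline_window) {
  stopifnot(length(baseline_window) == 2L)
  idx <- trace$time >= baseline_window[1] & trace$time <= baseline_window[2]
  if (!any(idx)) stop("empty baseline window", call. = FALSE)
  f0 <- mean(trace$values[idx])
  if (f0 == 0) stop("baseline mean is zero; cannot normalize", call. = FALSE)
  ratio_trace(trace$cell_id, trace$time, trace$values / f0, kind = "f_over_f0")
}

#' Centered moving-average smoothing
#'
#' Averages all samples within `width/2` seconds of each time point; windows
#' are truncated at the trace ends. `width = 0` returns the trace unchanged.
#' Used to pre-condition traces before slope/tangent estimation.
#'
#' @param trace a [fluor_trace] or [ratio_trace].
#' @param width window width in seconds (>= 0).
#' @return a trace of the same class with smoothed values.
#' @export
smooth_trace <- function(trace, width) {
  if (width < 0) stop("smoothing width must be >= 0", call. = FALSE)
  if (width == 0) return(trace)
  out <- trace
  out$values <- moving_average(trace$time, trace$values, width)
  out
}

moving_average <- function(t, v, width) {
  half <- width / 2
  lo <- findInterval(t - half - 1e-9, t) + 1L
  hi <- findInterval(t + half + 1e-9, t)
  cs <- cumsum(v)
  (cs[hi] - c(0, cs)[lo]) / (hi - lo + 1L)
}

#' Recovery half-time after washout
#'
#' Time from washout start to the first downward crossing of the midpoint
#' between a starting level and a baseline level, with linear interpolation
#' between samples. Later re-crossings are ignored (the washout phase is
#' assumed monotone on average). Returns `NA` with `crossed = FALSE` if the
#' signal never reaches the half level within the window.
#'
#' @param trace a [fluor_trace] or [ratio_trace].
#' @param washout_window numeric length-2 `c(start, end)` in seconds; must lie
#'   within the trace.
#' @param baseline_level signal level the trace recovers toward.
#' @param start_level signal level at washout start; must exceed
#'   `baseline_level`.
#' @return list with `halftime` (seconds, or `NA`), `crossed` (logical) and
#'   `half_level`.
#' @export
recovery_halftime <- function(trace, washout_window, baseline_level,
                              start_level) {
  stopifnot(length(washout_window) == 2L)
  if (washout_window[1] < min(trace$time) - 1e-9 ||
      washout_window[2] > max(trace$time) + 1e-9)
    stop("washout window lies outside the trace", call. = FALSE)
  if (start_level <= baseline_level)
    stop("start_level must exceed baseline_level", call. = FALSE)
  half <- (start_level + baseline_level) / 2
  idx <- trace$time >= washout_window[1] & trace$time <= washout_window[2]
  t <- trace$time[idx]; v <- trace$values[idx]
  if (length(t) < 2L) stop("washout window contains <2 samples", call. = FALSE)
  below <- v <= half
  if (!any(below)) return(list(halftime = NA_real_, crossed = FALSE,
                               half_level = half))
  j <- which(below)[1]
  tc <- if (j == 1L) t[1] else {
    # linear interpolation on the segment that crosses the half level
    t[j - 1] + (half - v[j - 1]) * (t[j] - t[j - 1]) / (v[j] - v[j - 1])
  }
  list(halftime = tc - washout_window[1], crossed = TRUE, half_level = half)
}
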