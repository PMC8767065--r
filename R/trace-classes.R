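#' Single-cell fluorescence trace
#'
#' Container for one cell's fluorescence signal versus time in a single
#' excitation/emission channel (e.g. the 340 nm or 380 nm channel of a
#' ratiometric indicator, or a single-channel probe such as Rh123).
#'
#' @param cell_id character scalar identifying the cell.
#' @param time numeric vector of acquisition times in seconds, strictly
#'   increasing, length >= 2.
#' @param values numeric vector of fluorescence values (arbitrary units),
#'   same length as `time`.
#' @param channel excitation/emission label, e.g. `"F340"`, `"F380"`,
#'   `"rh123"`.
#' @return an object of class `fluor_trace`.
#' @export
fluor_trace <- function(cell_id, time, values, channel = "F") {
  validate_trace_fields(cell_id, time, values)
  structure(
    list(cell_id = as.character(cell_id), time = as.numeric(time),
         values = as.numeric(values), channel = as.character(channel)),
    class = "fluor_trace")
}

#' Dimensionless ratio trace
#'
#' A per-cell dimensionless signal: either a two-excitation ratio
#' (F340/F380) or a signal normalized to its initial value (F/F0).
#'
#' @inheritParams fluor_trace
#' @param kind `"excitation_ratio"` (F340/F380) or `"f_over_f0"`.
#' @return an object of class `ratio_trace` (inherits `fluor_trace`).
#' @export
ratio_trace <- function(cell_id, time, values,
                        kind = c("excitation_ratio", "f_over_f0")) {
  kind <- match.arg(kind)
  validate_trace_fields(cell_id, time, values)
  if (any(!is.finite(values)))
    stop("ratio_trace: values must be finite", call. = FALSE)
  structure(
    list(cell_id = as.character(cell_id), time = as.numeric(time),
         values = as.numeric(values), kind = kind),
    class = c("ratio_trace", "fluor_trace"))
}

validate_trace_fields <- function(cell_id, time, values) {
  if (length(cell_id) != 1L) stop("cell_id must be a scalar", call. = FALSE)
  if (length(time) != length(values))
    stop("time and values must have equal length", call. = FALSE)
  if (length(time) < 2L) stop("trace needs at least 2 samples", call. = FALSE)
  if (anyNA(time) || anyNA(values))
    stop("missing samples are not supported; drop or re-export the trace",
         call. = FALSE)
  if (any(diff(time) <= 0))
    stop("time must be strictly increasing", call. = FALSE)
  invisible(TRUE)
}

#' @export
print.fluor_trace <- function(x, ...) {
  lab <- if (inherits(x, "ratio_trace")) x$kind else x$channel
  cat(sprintf("<%s> cell %s, %d samples, t = [%g, %g] s, %s\n",
              class(x)[1], x$cell_id, length(x$time),
              min(x$time), max(x$time), lab))
  invisible(x)
}

#' @export
as.data.frame.fluor_trace <- function(x, ...) {
  data.frame(cell_id = x$cell_id, time_s = x$time, value = x$values,
             channel = if (inherits(x, "ratio_trace")) x$kind else x$channel,
             stringsAsFactors = FALSE)
}

#' Event schedule for an imaging or plate experiment
#'
#' Named times (seconds) of agent additions and washouts, e.g. `glu_on`,
#' `glu_off`, `fccp_on`, `iono_on`. Times must be strictly increasing in the
#' order given; every window-based computation in the package is anchored to
#' these events.
#'
#' @param ... named numeric scalars, in chronological order.
#' @return an object of class `event_schedule` (a named numeric vector).
#' @examples
#' event_schedule(glu_on = 120, glu_off = 1020, fccp_on = 1620)
#' @export
event_schedule <- function(...) {
  ev <- c(...)
  if (length(ev) == 0) stop("event schedule is empty", call. = FALSE)
  if (is.null(names(ev)) || any(names(ev) == ""))
    stop("all events must be named", call. = FALSE)
  ev <- vapply(ev, as.numeric, numeric(1))
  if (any(diff(ev) <= 0))
    stop("event times must be strictly increasing", call. = FALSE)
  structure(ev, class = "event_schedule")
}

event_time <- function(events, name, required = TRUE) {
  if (!name %in% names(events)) {
    if (required)
      stop(sprintf("event schedule is missing required event '%s'", name),
           call. = FALSE)
    return(NA_real_)
  }
  unname(events[[name]])
}

#' @export
print.event_schedule <- function(x, ...) {
  cat("<event_schedule>\n")
  for (nm in names(x)) cat(sprintf("  %-10s %g s\n", nm, x[[nm]]))
  invisible(x)
}

#' Read an event schedule from a YAML file
#'
#' @param path YAML file mapping event names to times in seconds.
#' @return an `event_schedule`.
#' @export
read_event_schedule <- function(path) {
  lst <- yaml::read_yaml(path)
  do.call(event_schedule, lapply(lst, as.numeric))
}

#' Write an event schedule to YAML
#'
#' @param events an `event_schedule`.
#' @param path output file path.
#' @export
write_event_schedule <- function(events, path) {
  yaml::write_yaml(as.list(unclass(events)), path)
  invisible(path)
}
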