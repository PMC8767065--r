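# Viability endpoints: live/dead survival index and the kinetic MTT
# initial-rate metric.

#' Live/dead survival index
#'
#' Ratio of live (Syto-13 positive / EthD-1 negative) to dead (EthD-1
#' positive) cells, normalized to the same ratio in control cultures.
#' Conditions with zero dead cells have an undefined ratio: the index is
#' returned as `NA` with `defined = FALSE`, never silently imputed.
#'
#' @param counts list or one-row data.frame with `n_live` and `n_dead`.
#' @param control_counts same structure, for the control culture; its
#'   `n_dead` must be positive.
#' @return list with `index` (dimensionless or `NA`), `defined`, `ratio`,
#'   `control_ratio`.
#' @export
survival_index <- function(counts, control_counts) {
  n_live <- counts$n_live; n_dead <- counts$n_dead
  c_live <- control_counts$n_live; c_dead <- control_counts$n_dead
  if (any(c(n_live, n_dead, c_live, c_dead) < 0))
    stop("cell counts must be >= 0", call. = FALSE)
  if (n_live + n_dead == 0 || c_live + c_dead == 0)
    stop("counts must include at least one cell", call. = FALSE)
  if (c_dead == 0)
    stop("control has zero dead cells: control ratio undefined", call. = FALSE)
  control_ratio <- c_live / c_dead
  if (n_dead == 0)
    return(list(index = NA_real_, defined = FALSE, ratio = NA_real_,
                control_ratio = control_ratio))
  ratio <- n_live / n_dead
  list(index = ratio / control_ratio, defined = TRUE, ratio = ratio,
       control_ratio = control_ratio)
}

#' Survival indices for a table of conditions
#'
#' @param counts data.frame with columns `condition`, `n_live`, `n_dead`.
#' @param control name of the control condition (default `"control"`).
#' @return tibble with `condition`, `ratio`, `index`, `defined`.
#' @export
survival_index_table <- function(counts, control = "control") {
  ctrl <- counts[counts$condition == control, , drop = FALSE]
  if (nrow(ctrl) != 1L)
    stop(sprintf("control condition '%s' not found exactly once", control),
         call. = FALSE)
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    si <- survival_index(counts[i, ], ctrl)
    tibble::tibble(condition = counts$condition[i], ratio = si$ratio,
                   index = si$index, defined = si$defined)
  })
  do.call(rbind, rows)
}

#' Kinetic MTT initial rate
#'
#' Least-squares slope of background-corrected absorbance
#' (`a_signal - a_background`) versus time over the first `window_minutes`
#' after MTT addition. The initial rate of formazan formation reflects
#' neuronal dehydrogenase activity better than endpoint accumulation, which
#' is dominated by the slower glial reduction.
#'
#' @param kinetics data.frame with columns `time_min`, `a550` and `a_bg`
#'   (background-wavelength absorbance; the recording wavelength — 620 or
#'   650 nm — travels as metadata, not as a constant).
#' @param window_minutes fit window from time zero, minutes (default 10).
#' @param control_rate optional control rate (OD/min) for normalization;
#'   must be positive when given.
#' @return list with `rate` (OD/min), `rmse`, `n`, and `normalized_rate`
#'   (`NA` when no control rate is supplied).
#' @export
mtt_initial_rate <- function(kinetics, window_minutes = 10,
                             control_rate = NULL) {
  need <- c("time_min", "a550", "a_bg")
  if (!all(need %in% names(kinetics)))
    stop("kinetics needs columns time_min, a550, a_bg", call. = FALSE)
  idx <- kinetics$time_min <= window_minutes
  if (sum(idx) < 3L)
    stop("fewer than 3 samples inside the initial-rate window", call. = FALSE)
  corrected <- kinetics$a550[idx] - kinetics$a_bg[idx]
  fit <- ols_fit(kinetics$time_min[idx], corrected)
  norm <- NA_real_
  if (!is.null(control_rate)) {
    if (control_rate <= 0)
      stop("control rate must be positive", call. = FALSE)
    norm <- fit$slope / control_rate
  }
  list(rate = fit$slope, rmse = fit$rmse, n = fit$n, normalized_rate = norm)
}

#' MTT initial rates for a multi-well kinetics table
#'
#' @param mtt data.frame with columns `condition`, `well`, `time_min`,
#'   `a550`, `a_bg` (as produced by [gen_endpoint_tables()]).
#' @param window_minutes fit window, minutes.
#' @param control name of the control condition used for normalization; set
#'   `NULL` to skip normalization.
#' @return tibble with `condition`, `well`, `rate`, `normalized_rate`.
#' @export
mtt_rate_table <- function(mtt, window_minutes = 10, control = "control") {
  key <- interaction(mtt$condition, mtt$well, drop = TRUE)
  per_well <- lapply(split(mtt, key), function(d)
    tibble::tibble(condition = d$condition[1], well = d$well[1],
                   rate = mtt_initial_rate(d, window_minutes)$rate))
  out <- do.call(rbind, per_well)
  out <- out[order(out$condition, out$well), , drop = FALSE]
  if (!is.null(control)) {
    ctrl_rate <- mean(out$rate[out$condition == control])
    if (!is.finite(ctrl_rate) || ctrl_rate <= 0)
      stop("control rate is not positive; cannot normalize", call. = FALSE)
    out$normalized_rate <- out$rate / ctrl_rate
  }
  out
}
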