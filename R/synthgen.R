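# Synthetic cohort generators. Every generator is seeded through its params
# object and returns ground truth alongside the data, so each downstream
# estimator can be scored without re-deriving the truth.

# Observable lag window: lags shorter than the first-phase settling window
# cannot be separated from the first phase, and lags too close to washout
# leave no room for the secondary tangent fit.
lag_window_bounds <- function(params) {
  lo <- 60 + 3 * params$dcd_steepness
  hi <- (params$glu_off - params$glu_on) - 60 - 3 * params$dcd_steepness
  if (hi <= lo)
    stop("glutamate window too short for an observable DCD lag", call. = FALSE)
  c(lo, hi)
}

# Solve the parent log-normal location so that the median of the
# window-truncated distribution equals the target median.
calibrate_lag_meanlog <- function(median_target, sigma, lo, hi) {
  if (median_target <= lo || median_target >= hi)
    stop(sprintf(
      "lag_log_median (%g s) must lie inside the observable window [%g, %g] s",
      median_target, lo, hi), call. = FALSE)
  f <- function(mu) {
    fa <- stats::plnorm(lo, mu, sigma)
    fb <- stats::plnorm(hi, mu, sigma)
    stats::qlnorm((fa + fb) / 2, mu, sigma) - median_target
  }
  stats::uniroot(f, c(log(median_target) - 4, log(median_target) + 4),
                 tol = 1e-10)$root
}

sample_truncated_lags <- function(n, params) {
  b <- lag_window_bounds(params)
  mu <- calibrate_lag_meanlog(params$lag_log_median, params$lag_log_sigma,
                              b[1], b[2])
  fa <- stats::plnorm(b[1], mu, params$lag_log_sigma)
  fb <- stats::plnorm(b[2], mu, params$lag_log_sigma)
  stats::qlnorm(stats::runif(n, fa, fb), mu, params$lag_log_sigma)
}

# Deterministic calcium signal up to (and including) the end of the
# glutamate window; the DCD ramp is a logistic whose tangent-intersection
# onset equals glu_on + lag by construction (midpoint at onset + 2*steepness).
calcium_pre_washout <- function(t, p, dcd, lag) {
  v <- p$baseline_level +
    ifelse(t >= p$glu_on,
           p$first_phase_amplitude * (1 - exp(-(t - p$glu_on) / 5)), 0)
  if (isTRUE(dcd)) {
    tmid <- p$glu_on + lag + 2 * p$dcd_steepness
    v <- v + ifelse(t >= p$glu_on,
                    p$dcd_amplitude * stats::plogis((t - tmid) / p$dcd_steepness),
                    0)
  }
  v
}

calcium_signal <- function(t, p, dcd, lag) {
  v <- calcium_pre_washout(t, p, dcd, lag)
  k <- p$recovery_rate * p$lps_recovery_factor
  v_off <- calcium_pre_washout(p$glu_off, p, dcd, lag)
  post <- t > p$glu_off
  v[post] <- p$baseline_level +
    (v_off - p$baseline_level) * exp(-k * (t[post] - p$glu_off))
  fc <- t >= p$fccp_on
  dtf <- t[fc] - p$fccp_on
  v[fc] <- v[fc] +
    0.4 * p$first_phase_amplitude * (1 - exp(-dtf / 5)) * exp(-dtf / 60)
  io <- t >= p$iono_on
  sat <- p$baseline_level + p$first_phase_amplitude + p$dcd_amplitude + 0.5
  v[io] <- v[io] + (sat - v[io]) * (1 - exp(-(t[io] - p$iono_on) / 5))
  v
}

#' Generate a synthetic calcium-imaging cohort
#'
#' Draws per-cell DCD status and lag, builds F340/F380-style ratio traces
#' (baseline plateau, first-phase rise at `glu_on`, logistic secondary rise
#' for DCD cells, exponential post-washout recovery scaled by the LPS
#' factor, FCCP transient, ionomycin saturation) with additive Gaussian
#' noise, and returns the generating truth alongside.
#'
#' @param params a [synth_cohort_params()] object.
#' @return an object of class `trace_cohort`: list with `traces` (list of
#'   [ratio_trace]), `truth` (tibble: `cell_id`, `has_dcd`, `lag_true`,
#'   `onset_time`, `recovery_rate_true`, `recovery_frac_true`), `events`
#'   (an [event_schedule]) and `params`.
#' @export
gen_calcium_cohort <- function(params) {
  stopifnot(inherits(params, "synth_cohort_params"))
  set.seed(params$seed)
  p <- params
  t <- seq(0, p$iono_on + p$end_pad, by = p$sampling_interval)
  ids <- sprintf("cell%03d", seq_len(p$n_cells))
  dcd <- stats::runif(p$n_cells) < p$p_dcd
  lags <- rep(NA_real_, p$n_cells)
  lags[dcd] <- sample_truncated_lags(sum(dcd), p)
  k <- p$recovery_rate * p$lps_recovery_factor
  horizon <- max(t[t < p$fccp_on]) - p$glu_off
  traces <- vector("list", p$n_cells)
  for (i in seq_len(p$n_cells)) {
    v <- calcium_signal(t, p, dcd[i], lags[i]) +
      stats::rnorm(length(t), 0, p$noise_sd)
    traces[[i]] <- ratio_trace(ids[i], t, v, kind = "excitation_ratio")
  }
  names(traces) <- ids
  truth <- tibble::tibble(
    cell_id = ids, has_dcd = dcd, lag_true = lags,
    onset_time = p$glu_on + lags,
    recovery_rate_true = k,
    recovery_frac_true = 1 - exp(-k * horizon))
  structure(list(traces = traces, truth = truth,
                 events = params_events(p), params = p),
            class = "trace_cohort")
}

#' @export
print.trace_cohort <- function(x, ...) {
  cat(sprintf("<trace_cohort> %d traces (%s), %d DCD cells\n",
              length(x$traces),
              x$traces[[1]]$kind %||% x$traces[[1]]$channel,
              sum(x$truth$has_dcd %||% 0)))
  invisible(x)
}

#' Generate Rh123 mitochondrial-potential traces coupled to a calcium cohort
#'
#' For each cell of a calcium cohort, builds an Rh123 F/F0 trace:
#' depolarization (fluorescence rise) synchronized with that cell's DCD
#' onset, post-washout decay at the mitochondrial recovery rate scaled by
#' the same LPS factor, and an FCCP response whose release amplitude scales
#' with the polarization remaining at FCCP time; after FCCP the signal
#' decays as probe leak. Cells without DCD stay at F/F0 = 1 (within noise)
#' until FCCP.
#'
#' @param calcium_cohort a `trace_cohort` from [gen_calcium_cohort()].
#' @param params the same [synth_cohort_params()] object (seeded
#'   independently with `seed + 1`).
#' @param fccp_gain F/F0 release amplitude for a fully polarized cell.
#' @return a `trace_cohort` of `f_over_f0` [ratio_trace]s with truth columns
#'   `cell_id`, `has_dcd`, `onset_time`, `mito_recovery_rate_true`,
#'   `depol_at_fccp_true`.
#' @export
gen_mito_cohort <- function(calcium_cohort, params, fccp_gain = 0.8) {
  stopifnot(inherits(calcium_cohort, "trace_cohort"),
            inherits(params, "synth_cohort_params"))
  truth <- calcium_cohort$truth
  if (!identical(truth$cell_id, names(calcium_cohort$traces)))
    stop("pairing error: cohort truth and traces disagree on cell ids",
         call. = FALSE)
  set.seed(params$seed + 1L)
  p <- params
  t <- calcium_cohort$traces[[1]]$time
  km <- p$mito_recovery_rate * p$lps_recovery_factor
  M <- p$mito_amplitude
  leak_tau <- 60
  traces <- vector("list", nrow(truth))
  depol_fccp <- numeric(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    if (truth$has_dcd[i]) {
      tmid <- truth$onset_time[i] + 2 * p$dcd_steepness
      depol <- ifelse(t >= p$glu_on & t <= p$glu_off,
                      M * stats::plogis((t - tmid) / p$dcd_steepness), 0)
      d_off <- M * stats::plogis((p$glu_off - tmid) / p$dcd_steepness)
      post <- t > p$glu_off & t < p$fccp_on
      depol[post] <- d_off * exp(-km * (t[post] - p$glu_off))
      d_fccp <- d_off * exp(-km * (p$fccp_on - p$glu_off))
    } else {
      depol <- rep(0, length(t))
      d_fccp <- 0
    }
    release <- fccp_gain * (1 - d_fccp / M)
    fc <- t >= p$fccp_on
    dtf <- t[fc] - p$fccp_on
    depol[fc] <- d_fccp * exp(-dtf / leak_tau) +
      release * (1 - exp(-dtf / 5)) * exp(-dtf / leak_tau)
    v <- 1 + depol + stats::rnorm(length(t), 0, p$noise_sd)
    traces[[i]] <- ratio_trace(truth$cell_id[i], t, v, kind = "f_over_f0")
    depol_fccp[i] <- d_fccp
  }
  names(traces) <- truth$cell_id
  mito_truth <- tibble::tibble(
    cell_id = truth$cell_id, has_dcd = truth$has_dcd,
    onset_time = truth$onset_time,
    mito_recovery_rate_true = km,
    depol_at_fccp_true = depol_fccp)
  structure(list(traces = traces, truth = mito_truth,
                 events = params_events(p), params = p),
            class = "trace_cohort")
}

#' Generate sodium or plasma-membrane-potential traces
#'
#' Sodium (SBFI-ratio-style) traces rise at `glu_on` in every cell and
#' recover after washout strictly more slowly than the paired calcium
#' signal (half the rate; DCD cells slower still). DiBAC traces rise at
#' `glu_on` (plasma-membrane depolarization) and recover partially.
#' With `glu = FALSE` a flat no-glutamate control is produced.
#'
#' @param kind `"sodium"` or `"dibac"`.
#' @param params a [synth_cohort_params()] object (seeded with `seed + 2`).
#' @param calcium_cohort optional paired cohort; if supplied, DCD flags are
#'   shared with it, otherwise fresh flags are drawn.
#' @param glu if `FALSE`, no stimulation is applied (control trace).
#' @return a `trace_cohort` of `f_over_f0` [ratio_trace]s with truth columns
#'   `cell_id`, `has_dcd`, `recovery_rate_true`.
#' @export
gen_ion_cohort <- function(kind = c("sodium", "dibac"), params,
                           calcium_cohort = NULL, glu = TRUE) {
  kind <- match.arg(kind)
  stopifnot(inherits(params, "synth_cohort_params"))
  set.seed(params$seed + 2L)
  p <- params
  t <- seq(0, p$iono_on + p$end_pad, by = p$sampling_interval)
  if (!is.null(calcium_cohort)) {
    ids <- calcium_cohort$truth$cell_id
    dcd <- calcium_cohort$truth$has_dcd
  } else {
    ids <- sprintf("cell%03d", seq_len(p$n_cells))
    dcd <- stats::runif(p$n_cells) < p$p_dcd
  }
  amp <- if (kind == "sodium") 0.8 else 0.6
  tau_rise <- if (kind == "sodium") 15 else 10
  base_rate <- if (kind == "sodium") 0.5 else 0.3
  traces <- vector("list", length(ids))
  k_cell <- numeric(length(ids))
  for (i in seq_along(ids)) {
    k <- base_rate * p$recovery_rate * p$lps_recovery_factor *
      (if (dcd[i]) 0.6 else 1)
    k_cell[i] <- k
    if (glu) {
      v <- 1 + ifelse(t >= p$glu_on & t <= p$glu_off,
                      amp * (1 - exp(-(t - p$glu_on) / tau_rise)), 0)
      v_off <- 1 + amp * (1 - exp(-(p$glu_off - p$glu_on) / tau_rise))
      post <- t > p$glu_off
      v[post] <- 1 + (v_off - 1) * exp(-k * (t[post] - p$glu_off))
    } else {
      v <- rep(1, length(t))
    }
    v <- v + stats::rnorm(length(t), 0, p$noise_sd)
    traces[[i]] <- ratio_trace(ids[i], t, v, kind = "f_over_f0")
  }
  names(traces) <- ids
  truth <- tibble::tibble(cell_id = ids, has_dcd = dcd,
                          recovery_rate_true = k_cell)
  structure(list(traces = traces, truth = truth,
                 events = params_events(p), params = p, kind = kind),
            class = "trace_cohort")
}

#' Generate a synthetic extracellular-flux (OCR) plate
#'
#' Per-well OCR per measurement cycle with sequential injections: an acute
#' glutamate response decaying back toward baseline, an FCCP segment at
#' `fccp_fold` times basal respiration, and a post-antimycin/rotenone floor
#' at the non-mitochondrial OCR. A shared linear instrument drift affects
#' every well; blank wells carry only drift and noise. Ground-truth metrics
#' satisfy `maximal = basal + src` exactly.
#'
#' @param params a [synth_plate_params()] object.
#' @return list with `plate` (a [flux_plate]) and `truth` (tibble: `well`,
#'   `pre_ocr`, `nocr`, `basal`, `maximal`, `src`, `acute_glu`).
#' @export
gen_ocr_plate <- function(params) {
  stopifnot(inherits(params, "synth_plate_params"))
  set.seed(params$seed)
  p <- params
  wells <- sprintf("W%02d", seq_len(p$n_wells))
  blank <- seq_len(p$n_wells) <= p$n_blank_wells
  period <- sum(p$cycle_structure)
  times <- (seq_len(p$n_cycles) - 1) * period +
    p$cycle_structure[1] + p$cycle_structure[2] + p$cycle_structure[3] / 2
  inj <- p$injections
  basal_total <- stats::runif(p$n_wells, p$basal_ocr_range[1],
                              p$basal_ocr_range[2])
  nocr <- p$nocr_fraction * basal_total
  basal_resp <- basal_total - nocr
  seg_of <- function(agent) {
    j <- match(agent, inj$agent)
    if (is.na(j)) return(NULL)
    from <- inj$cycle[j]
    to <- if (j < nrow(inj)) inj$cycle[j + 1] - 1L else p$n_cycles
    seq.int(from, to)
  }
  ocr <- matrix(0, p$n_wells, p$n_cycles, dimnames = list(wells, NULL))
  for (w in seq_len(p$n_wells)) {
    if (blank[w]) next
    v <- rep(basal_total[w], p$n_cycles)
    sg <- seg_of("glu")
    if (!is.null(sg)) {
      peak <- p$acute_glu_fold * basal_total[w]
      v[sg] <- basal_total[w] + (peak - basal_total[w]) *
        exp(-(sg - sg[1]) / 2)
    }
    sf <- seg_of("fccp")
    if (!is.null(sf)) v[sf] <- nocr[w] + p$fccp_fold * basal_resp[w]
    sa <- seg_of("antrot")
    if (!is.null(sa)) v[sa] <- nocr[w]
    ocr[w, ] <- v
  }
  drift <- p$drift_amplitude *
    (seq_len(p$n_cycles) - 1) / max(1, p$n_cycles - 1)
  ocr <- ocr + matrix(drift, p$n_wells, p$n_cycles, byrow = TRUE) +
    matrix(stats::rnorm(p$n_wells * p$n_cycles, 0, p$noise_sd),
           p$n_wells, p$n_cycles)
  plate <- flux_plate(ocr = ocr, blank = blank, times = times,
                      injections = inj)
  truth <- tibble::tibble(
    well = wells[!blank],
    pre_ocr = basal_total[!blank],
    nocr = nocr[!blank],
    basal = basal_resp[!blank],
    maximal = p$fccp_fold * basal_resp[!blank],
    src = (p$fccp_fold - 1) * basal_resp[!blank],
    acute_glu = (p$acute_glu_fold - 1) * basal_total[!blank])
  list(plate = plate, truth = truth)
}

#' Generate synthetic endpoint tables
#'
#' Live/dead counts drawn binomially from per-condition survival
#' probabilities; kinetic MTT absorbance at the signal and background
#' wavelengths (linear initial phase, then saturation); and per-cell soma
#' contour areas before/after treatment with multiplicative,
#' mean-unbiased per-experiment condition effects.
#'
#' @param params a [synth_endpoint_params()] object.
#' @return list of tibbles: `viability` (condition, n_live, n_dead,
#'   survival_p_true), `mtt` (condition, well, time_min, a550, a_bg),
#'   `mtt_truth` (condition, well, rate_true), `areas` (experiment,
#'   condition, cell_id, area_before, area_after, fold_true).
#' @export
gen_endpoint_tables <- function(params) {
  stopifnot(inherits(params, "synth_endpoint_params"))
  set.seed(params$seed)
  p <- params
  cond <- p$conditions
  n <- p$n_cells_viability
  n_dead <- stats::rbinom(nrow(cond), n, 1 - cond$survival_p)
  viability <- tibble::tibble(
    condition = cond$condition, n_live = n - n_dead, n_dead = n_dead,
    survival_p_true = cond$survival_p)

  tm <- seq(0, 30, by = 1)
  lin <- p$mtt_linear_min
  mtt <- list(); mtt_truth <- list()
  for (ci in seq_len(nrow(cond))) {
    for (w in seq_len(p$mtt_wells)) {
      r <- cond$mtt_rate[ci] * exp(stats::rnorm(1, 0, 0.05) - 0.05^2 / 2)
      curve <- ifelse(tm <= lin, r * tm,
                      r * lin + r * p$mtt_sat_tau *
                        (1 - exp(-(tm - lin) / p$mtt_sat_tau)))
      a550 <- 0.2 + curve + p$mtt_background +
        stats::rnorm(length(tm), 0, p$mtt_noise_sd)
      a_bg <- p$mtt_background + stats::rnorm(length(tm), 0, p$mtt_noise_sd)
      mtt[[length(mtt) + 1L]] <- tibble::tibble(
        condition = cond$condition[ci], well = sprintf("w%d", w),
        time_min = tm, a550 = a550, a_bg = a_bg,
        background_wavelength_nm = p$background_wavelength_nm)
      mtt_truth[[length(mtt_truth) + 1L]] <- tibble::tibble(
        condition = cond$condition[ci], well = sprintf("w%d", w),
        rate_true = r)
    }
  }

  areas <- list()
  for (e in seq_len(p$n_experiments)) {
    for (ci in seq_len(nrow(cond))) {
      fold_e <- cond$area_fold[ci] *
        exp(stats::rnorm(1, 0, p$area_experiment_sd) -
              p$area_experiment_sd^2 / 2)
      before <- stats::rlnorm(p$cells_per_experiment, log(200), 0.3)
      jitter <- exp(stats::rnorm(p$cells_per_experiment, 0, p$area_cell_sd) -
                      p$area_cell_sd^2 / 2)
      areas[[length(areas) + 1L]] <- tibble::tibble(
        experiment = e, condition = cond$condition[ci],
        cell_id = sprintf("e%02d_c%02d", e, seq_len(p$cells_per_experiment)),
        area_before = before, area_after = before * fold_e * jitter,
        fold_true = fold_e)
    }
  }
  list(viability = viability,
       mtt = do.call(rbind, mtt),
       mtt_truth = do.call(rbind, mtt_truth),
       areas = do.call(rbind, areas))
}
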