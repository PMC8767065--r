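#' Parameters of the synthetic imaging cohort generator
#'
#' Full parameterization of the generative model for single-cell calcium /
#' Rh123 / Na+ traces. Defaults describe a cortical-culture experiment:
#' 2-min baseline, 15-min glutamate exposure, 10-min washout, then FCCP and
#' ionomycin.
#'
#' @param n_cells number of cells in the cohort.
#' @param sampling_interval imaging interval, seconds.
#' @param glu_on,glu_off,fccp_on,iono_on event times, seconds, strictly
#'   increasing; the trace ends `end_pad` seconds after `iono_on`.
#' @param p_dcd probability that a cell develops delayed calcium
#'   deregulation (DCD) within the glutamate window.
#' @param lag_log_median target median of the observed lag-DCD, seconds.
#'   Lags are drawn from a log-normal truncated to the observable window
#'   (see the methods vignette); the parent location is solved so the
#'   truncated median equals this value.
#' @param lag_log_sigma log-scale shape of the lag distribution.
#' @param first_phase_amplitude amplitude of the first-phase rise, ratio
#'   units above baseline.
#' @param dcd_amplitude amplitude of the secondary (DCD) rise, ratio units.
#' @param dcd_steepness logistic time constant of the secondary rise,
#'   seconds; the tangent-intersection onset of the ramp equals the drawn
#'   lag by construction.
#' @param recovery_rate exponential rate of the post-washout decay toward
#'   baseline, 1/seconds.
#' @param lps_recovery_factor multiplicative modifier in (0, 1] applied to
#'   `recovery_rate` (and to the mitochondrial recovery rate); models the
#'   slowing of recovery by lipopolysaccharide.
#' @param mito_recovery_rate exponential rate of Rh123 F/F0 decay after
#'   washout, 1/seconds (before the LPS factor).
#' @param mito_amplitude Rh123 F/F0 depolarization amplitude in DCD cells.
#' @param baseline_level resting F340/F380 ratio.
#' @param noise_sd additive Gaussian noise, ratio units; default 2% of
#'   `first_phase_amplitude`.
#' @param end_pad seconds recorded after `iono_on`.
#' @param seed integer RNG seed; identical seeds regenerate bit-identical
#'   cohorts.
#' @return an object of class `synth_cohort_params`.
#' @seealso [preset_cohort_params()] for the calibrated cortical and
#'   cerebellar presets.
#' @export
synth_cohort_params <- function(n_cells = 288,
                                sampling_interval = 5,
                                glu_on = 120, glu_off = 1020,
                                fccp_on = 1620, iono_on = 1800,
                                p_dcd = 0.85,
                                lag_log_median = 180,
                                lag_log_sigma = 0.85,
                                first_phase_amplitude = 0.5,
                                dcd_amplitude = 1.5,
                                dcd_steepness = 10,
                                recovery_rate = 0.004,
                                lps_recovery_factor = 1,
                                mito_recovery_rate = 0.003,
                                mito_amplitude = 1.0,
                                baseline_level = 0.5,
                                noise_sd = 0.02 * first_phase_amplitude,
                                end_pad = 120,
                                seed = 1L) {
  ev <- c(glu_on = glu_on, glu_off = glu_off, fccp_on = fccp_on,
          iono_on = iono_on)
  if (any(diff(ev) <= 0) || glu_on <= 0)
    stop("schedule error: event times must be strictly increasing and positive",
         call. = FALSE)
  if (p_dcd < 0 || p_dcd > 1) stop("p_dcd must lie in [0, 1]", call. = FALSE)
  if (recovery_rate <= 0) stop("recovery_rate must be > 0", call. = FALSE)
  if (lps_recovery_factor <= 0 || lps_recovery_factor > 1)
    stop("lps_recovery_factor must lie in (0, 1]", call. = FALSE)
  if (sampling_interval <= 0) stop("sampling_interval must be > 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(
    n_cells = as.integer(n_cells), sampling_interval = sampling_interval,
    glu_on = glu_on, glu_off = glu_off, fccp_on = fccp_on, iono_on = iono_on,
    p_dcd = p_dcd, lag_log_median = lag_log_median,
    lag_log_sigma = lag_log_sigma,
    first_phase_amplitude = first_phase_amplitude,
    dcd_amplitude = dcd_amplitude, dcd_steepness = dcd_steepness,
    recovery_rate = recovery_rate, lps_recovery_factor = lps_recovery_factor,
    mito_recovery_rate = mito_recovery_rate, mito_amplitude = mito_amplitude,
    baseline_level = baseline_level, noise_sd = noise_sd,
    end_pad = end_pad, seed = as.integer(seed)),
    class = "synth_cohort_params")
}

#' Calibrated cohort presets
#'
#' `"cortical"`: observed lag-DCD median 180 s (IQR-derived log-sigma 0.85),
#' n = 288 cells, DCD fraction 0.85. `"cerebellar"`: median 530 s
#' (log-sigma 0.71), n = 298 cells, DCD fraction 0.70.
#'
#' @param preset `"cortical"` or `"cerebellar"`.
#' @param ... overrides passed on to [synth_cohort_params()].
#' @return a `synth_cohort_params` object.
#' @export
preset_cohort_params <- function(preset = c("cortical", "cerebellar"), ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    cortical   = list(n_cells = 288, p_dcd = 0.85,
                      lag_log_median = 180, lag_log_sigma = 0.85),
    cerebellar = list(n_cells = 298, p_dcd = 0.70,
                      lag_log_median = 530, lag_log_sigma = 0.71))
  args <- utils::modifyList(base, list(...))
  do.call(synth_cohort_params, args)
}

#' @export
print.synth_cohort_params <- function(x, ...) {
  cat(sprintf(paste0(
    "<synth_cohort_params> n_cells=%d, dt=%gs, p_dcd=%.2f,\n",
    "  lag median=%gs (log-sigma %.2f), recovery=%g/s x factor %.2f, seed=%d\n"),
    x$n_cells, x$sampling_interval, x$p_dcd, x$lag_log_median,
    x$lag_log_sigma, x$recovery_rate, x$lps_recovery_factor, x$seed))
  invisible(x)
}

#' Parameters of the synthetic extracellular-flux plate generator
#'
#' Emulates a 24-well plate respirometry run with mix/wait/measure cycles,
#' sequential injections, and dedicated cell-free blank wells carrying only
#' instrument drift and noise.
#'
#' @param n_wells total wells on the plate.
#' @param n_blank_wells number of cell-free blank wells (>= 1).
#' @param basal_ocr_range length-2 range (pmol O2/min) from which per-well
#'   basal OCR is drawn uniformly.
#' @param injections data.frame with columns `agent` and `cycle` (first
#'   measurement cycle affected by each injection), in injection order.
#' @param n_cycles number of measurement cycles.
#' @param cycle_structure length-3 `(mix, wait, measure)` durations, minutes.
#' @param fccp_fold maximal respiration as a multiple of basal respiration.
#' @param nocr_fraction non-mitochondrial OCR as a fraction of total basal
#'   OCR.
#' @param acute_glu_fold peak total OCR right after glutamate injection as a
#'   multiple of the pre-injection OCR.
#' @param drift_amplitude linear instrument drift over the run, pmol O2/min
#'   (shared by all wells; removed exactly by blank correction when noise is
#'   zero).
#' @param noise_sd additive Gaussian noise, pmol O2/min.
#' @param seed integer RNG seed.
#' @return an object of class `synth_plate_params`.
#' @export
synth_plate_params <- function(n_wells = 24, n_blank_wells = 4,
                               basal_ocr_range = c(100, 200),
                               injections = data.frame(
                                 agent = c("glu", "fccp", "antrot"),
                                 cycle = c(4L, 9L, 12L)),
                               n_cycles = 15,
                               cycle_structure = c(3, 2, 3),
                               fccp_fold = 2.1,
                               nocr_fraction = 0.1,
                               acute_glu_fold = 1.7,
                               drift_amplitude = 5,
                               noise_sd = 3,
                               seed = 1L) {
  if (n_blank_wells < 1) stop("need at least one blank well", call. = FALSE)
  if (n_blank_wells >= n_wells)
    stop("blank wells must leave at least one sample well", call. = FALSE)
  if (any(basal_ocr_range <= 0) || diff(basal_ocr_range) < 0)
    stop("basal OCR range must be positive and ordered", call. = FALSE)
  if (length(cycle_structure) != 3L || any(cycle_structure <= 0))
    stop("cycle_structure must be three positive durations (mix, wait, measure)",
         call. = FALSE)
  injections$cycle <- as.integer(injections$cycle)
  if (any(injections$cycle > n_cycles) || any(injections$cycle < 2L))
    stop("schedule error: injection cycle outside the plate's cycle range",
         call. = FALSE)
  if (any(diff(injections$cycle) <= 0))
    stop("schedule error: injections must be in increasing cycle order",
         call. = FALSE)
  structure(list(
    n_wells = as.integer(n_wells), n_blank_wells = as.integer(n_blank_wells),
    basal_ocr_range = basal_ocr_range, injections = injections,
    n_cycles = as.integer(n_cycles), cycle_structure = cycle_structure,
    fccp_fold = fccp_fold, nocr_fraction = nocr_fraction,
    acute_glu_fold = acute_glu_fold, drift_amplitude = drift_amplitude,
    noise_sd = noise_sd, seed = as.integer(seed)),
    class = "synth_plate_params")
}

#' Parameters of the synthetic endpoint-assay generator
#'
#' Conditions and noise for the live/dead counting, kinetic MTT and
#' soma-area endpoints. Default survival probabilities give live/dead odds
#' ratios of 1.00 (control), 0.84 (LPS), 0.70 (Glu) and 0.68 (Glu+LPS);
#' default area folds are 1.427 (Glu) and 1.22 (Glu+LPS).
#'
#' @param conditions data.frame with columns `condition`, `survival_p`
#'   (per-cell probability of staying alive), `mtt_rate` (formazan OD/min),
#'   `area_fold` (multiplicative soma-area change).
#' @param n_cells_viability cells scored per condition in the live/dead count.
#' @param mtt_wells wells per condition in the MTT kinetics.
#' @param mtt_linear_min duration of the initial linear phase, minutes.
#' @param mtt_sat_tau saturation time constant after the linear phase, minutes.
#' @param mtt_background constant background absorbance.
#' @param background_wavelength_nm recorded background wavelength metadata.
#' @param mtt_noise_sd absorbance noise sd.
#' @param n_experiments independent experiments for the area endpoint.
#' @param cells_per_experiment cells contoured per experiment and condition.
#' @param area_experiment_sd log-scale sd of the per-experiment area fold.
#' @param area_cell_sd log-scale sd of the per-cell area jitter.
#' @param seed integer RNG seed.
#' @return an object of class `synth_endpoint_params`.
#' @export
synth_endpoint_params <- function(
    conditions = data.frame(
      condition = c("control", "lps", "glu", "glu_lps"),
      survival_p = c(0.900, 0.883, 0.863, 0.860),
      mtt_rate = c(0.010, 0.008, 0.007, 0.006),
      area_fold = c(1.0, 1.0, 1.427, 1.22)),
    n_cells_viability = 600,
    mtt_wells = 8, mtt_linear_min = 10, mtt_sat_tau = 10,
    mtt_background = 0.05, background_wavelength_nm = 650,
    mtt_noise_sd = 0.002,
    n_experiments = 30, cells_per_experiment = 20,
    area_experiment_sd = 0.125, area_cell_sd = 0.05,
    seed = 1L) {
  if (any(conditions$survival_p < 0 | conditions$survival_p > 1))
    stop("survival probabilities must lie in [0, 1]", call. = FALSE)
  if (any(conditions$area_fold <= 0))
    stop("area folds must be positive", call. = FALSE)
  structure(list(
    conditions = conditions, n_cells_viability = as.integer(n_cells_viability),
    mtt_wells = as.integer(mtt_wells), mtt_linear_min = mtt_linear_min,
    mtt_sat_tau = mtt_sat_tau, mtt_background = mtt_background,
    background_wavelength_nm = background_wavelength_nm,
    mtt_noise_sd = mtt_noise_sd,
    n_experiments = as.integer(n_experiments),
    cells_per_experiment = as.integer(cells_per_experiment),
    area_experiment_sd = area_experiment_sd, area_cell_sd = area_cell_sd,
    seed = as.integer(seed)),
    class = "synth_endpoint_params")
}

# Event schedule implied by cohort params.
params_events <- function(params) {
  event_schedule(glu_on = params$glu_on, glu_off = params$glu_off,
                 fccp_on = params$fccp_on, iono_on = params$iono_on)
}
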