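# Generators: seeded determinism, calibration, coupling contracts, and the
# ground truth shipped with every cohort.

test_that("all generators are bit-identical under the same seed", {
  p <- small_cohort_params(seed = 5)
  expect_identical(gen_calcium_cohort(p), gen_calcium_cohort(p))
  ca <- gen_calcium_cohort(p)
  expect_identical(gen_mito_cohort(ca, p), gen_mito_cohort(ca, p))
  expect_identical(gen_ion_cohort("sodium", p), gen_ion_cohort("sodium", p))
  pp <- synth_plate_params(seed = 5)
  expect_identical(gen_ocr_plate(pp), gen_ocr_plate(pp))
  ep <- synth_endpoint_params(seed = 5)
  expect_identical(gen_endpoint_tables(ep), gen_endpoint_tables(ep))
})

test_that("DCD fraction falls inside the binomial interval around p_dcd", {
  p <- preset_cohort_params("cortical", n_cells = 500, p_dcd = 0.8, seed = 21)
  co <- gen_calcium_cohort(p)
  ci <- qbinom(c(0.025, 0.975), 500, 0.8) / 500
  frac <- mean(co$truth$has_dcd)
  expect_gte(frac, ci[1])
  expect_lte(frac, ci[2])
})

test_that("cortical preset lags have the calibrated median", {
  p <- preset_cohort_params("cortical", seed = 33)  # n = 288
  co <- gen_calcium_cohort(p)
  med <- median(co$truth$lag_true, na.rm = TRUE)
  expect_lt(abs(med - 180) / 180, 0.10)
})

test_that("cohort traces have the constructed phase structure", {
  p <- small_cohort_params(seed = 8)
  co <- gen_calcium_cohort(p)
  tr <- co$traces[[which(co$truth$has_dcd)[1]]]
  t <- tr$time
  base <- mean(tr$values[t < p$glu_on])
  expect_equal(base, p$baseline_level, tolerance = 0.01)
  # first phase elevates the plateau, DCD elevates it further by glu_off
  plateau <- mean(tr$values[t > p$glu_on + 30 & t < p$glu_on + 60])
  expect_gt(plateau, base + 0.8 * p$first_phase_amplitude)
  v_off <- tr$values[which.min(abs(t - p$glu_off))]
  expect_gt(v_off, plateau + 0.5 * p$dcd_amplitude)
  # ionomycin saturates at the top of the dynamic range
  expect_gt(mean(tr$values[t > p$iono_on + 30]),
            p$baseline_level + p$first_phase_amplitude + p$dcd_amplitude)
  # invalid schedules are rejected
  expect_error(synth_cohort_params(glu_on = 500, glu_off = 400), "schedule")
  expect_error(synth_cohort_params(p_dcd = 1.2), "p_dcd")
  expect_error(synth_cohort_params(lps_recovery_factor = 0), "factor")
})

test_that("Rh123 traces couple to the calcium cohort", {
  p <- small_cohort_params(seed = 13)
  ca <- gen_calcium_cohort(p)
  mi <- gen_mito_cohort(ca, p)
  # depolarization onset equals the calcium DCD onset (shared truth)
  expect_identical(mi$truth$onset_time, ca$truth$onset_time)
  expect_identical(mi$truth$cell_id, ca$truth$cell_id)

  # a cell without DCD stays at F/F0 = 1 (within noise) until FCCP
  i0 <- which(!mi$truth$has_dcd)[1]
  tr <- mi$traces[[i0]]
  pre_fccp <- tr$values[tr$time < p$fccp_on]
  expect_lt(max(abs(pre_fccp - 1)), 6 * p$noise_sd)

  # mismatched pairing is an error
  ca_bad <- ca
  ca_bad$truth <- ca_bad$truth[rev(seq_len(nrow(ca_bad$truth))), ]
  expect_error(gen_mito_cohort(ca_bad, p), "pairing")
})

test_that("slower LPS recovery flattens the post-washout Rh123 slope", {
  slopes <- vapply(c(1.0, 0.5), function(f) {
    p <- small_cohort_params(seed = 17, lps_recovery_factor = f)
    ca <- gen_calcium_cohort(p)
    mi <- gen_mito_cohort(ca, p)
    res <- analyze_mito_cohort(mi)
    mean(res$slope[mi$truth$has_dcd])
  }, numeric(1))
  expect_lt(slopes[1], 0)                       # recovery = negative slope
  expect_lt(abs(slopes[2]), abs(slopes[1]))     # factor 0.5 -> flatter
})

test_that("sodium recovers more slowly than calcium in the same cell", {
  p <- small_cohort_params(seed = 19, noise_sd = 0.002)
  ca <- gen_calcium_cohort(p)
  na <- gen_ion_cohort("sodium", p, calcium_cohort = ca)
  ev <- ca$events
  washout <- c(ev[["glu_off"]], ev[["fccp_on"]] - 5)
  for (i in c(1, 7, 20)) {
    tr_ca <- ca$traces[[i]]; tr_na <- na$traces[[i]]
    ht <- function(tr) {
      base <- mean(tr$values[tr$time < ev[["glu_on"]]])
      start <- tr$values[which.min(abs(tr$time - ev[["glu_off"]]))]
      recovery_halftime(tr, washout, base, start)$halftime
    }
    h_ca <- ht(tr_ca); h_na <- ht(tr_na)
    if (!is.na(h_ca) && !is.na(h_na)) expect_gt(h_na, h_ca)
  }
  # no-glutamate control stays flat within noise
  ctrl <- gen_ion_cohort("sodium", p, glu = FALSE)
  expect_lt(max(abs(ctrl$traces[[1]]$values - 1)), 6 * p$noise_sd)
  expect_error(gen_ion_cohort("potassium", p), "arg")
})

test_that("OCR plates carry exact ground-truth identities and clean blanks", {
  pp <- synth_plate_params(seed = 23, noise_sd = 0)
  gp <- gen_ocr_plate(pp)
  # blank wells: drift only, no injection response (constant after detrend)
  bl <- gp$plate$ocr[gp$plate$blank, , drop = FALSE]
  drift <- colMeans(bl)
  expect_equal(max(abs(sweep(bl, 2, drift))), 0)
  expect_lt(max(abs(diff(drift))), pp$drift_amplitude)
  # ground truth identity holds to floating tolerance
  expect_equal(gp$truth$maximal, gp$truth$basal + gp$truth$src,
               tolerance = 1e-12)
  # noiseless plate: recovered metrics equal ground truth
  fm <- compute_flux_metrics(blank_correct(gp$plate))
  expect_equal(fm$basal, gp$truth$basal, tolerance = 1e-12)
  expect_equal(fm$maximal, gp$truth$maximal, tolerance = 1e-12)
  expect_equal(fm$nocr, gp$truth$nocr, tolerance = 1e-12)
  expect_equal(fm$acute_glu, gp$truth$acute_glu, tolerance = 1e-12)
  # injections beyond the plate are a schedule error
  expect_error(synth_plate_params(
    injections = data.frame(agent = "glu", cycle = 99L)), "schedule")
  expect_error(synth_plate_params(n_blank_wells = 0), "blank")
})

test_that("endpoint tables match their generating parameters", {
  # survival probability 0.5 at n = 1000: live fraction inside binomial CI
  ep <- synth_endpoint_params(
    conditions = data.frame(condition = c("control", "x"),
                            survival_p = c(0.9, 0.5),
                            mtt_rate = c(0.01, 0.01),
                            area_fold = c(1, 1)),
    n_cells_viability = 1000, seed = 31)
  tab <- gen_endpoint_tables(ep)$viability
  ci <- qbinom(c(0.025, 0.975), 1000, 0.5) / 1000
  frac <- tab$n_live[tab$condition == "x"] / 1000
  expect_gte(frac, ci[1]); expect_lte(frac, ci[2])

  # area factor 1.427 -> mean change close to +42.7%
  ep2 <- synth_endpoint_params(seed = 37)
  areas <- gen_endpoint_tables(ep2)$areas
  sa <- summarize_area_change(areas)
  glu_pct <- sa$mean_pct[sa$condition == "glu"]
  expect_lt(abs(glu_pct - 42.7), 10)

  # noiseless MTT kinetics: per-well initial rate recovered exactly
  ep3 <- synth_endpoint_params(mtt_noise_sd = 0, seed = 41)
  out <- gen_endpoint_tables(ep3)
  one <- out$mtt[out$mtt$condition == "glu" & out$mtt$well == "w1", ]
  truth <- out$mtt_truth
  r <- mtt_initial_rate(one)$rate
  expect_equal(r, truth$rate_true[truth$condition == "glu" &
                                    truth$well == "w1"],
               tolerance = 1e-10)
  expect_error(synth_endpoint_params(
    conditions = data.frame(condition = "a", survival_p = -0.1,
                            mtt_rate = 0.01, area_fold = 1)), "probabilities")
})

test_that("lowering the LPS factor strictly lowers true recovery fractions", {
  fracs <- vapply(c(1.0, 0.7, 0.4), function(f) {
    p <- small_cohort_params(seed = 3, lps_recovery_factor = f)
    gen_calcium_cohort(p)$truth$recovery_frac_true[1]
  }, numeric(1))
  expect_true(all(diff(fracs) < 0))
})
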