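# DCD classification, tangent-intersection lag, recovery index and
# sister-control normalization.

test_that("monophasic traces are not classified as DCD", {
  ev <- default_events()
  tr <- make_monophasic_trace(ev)
  cls <- classify_dcd(tr, ev)
  expect_false(cls$has_dcd)
  expect_null(cls$rise_idx)
})

test_that("generated DCD status is recovered from the traces", {
  p <- small_cohort_params(seed = 2)
  co <- gen_calcium_cohort(p)
  res <- analyze_dcd_cohort(co)
  expect_gte(mean(res$has_dcd == co$truth$has_dcd), 0.95)
})

test_that("a rise exactly at threshold is negative (strict inequality)", {
  # exactly binary-representable levels so the tie is a true tie:
  # baseline 0, plateau 4, min_rise_frac 0.25 -> threshold = 1 exactly
  ev <- default_events()
  t <- seq(0, max(ev) + 100, by = 5)
  v <- ifelse(t < ev[["glu_on"]], 0, 4)
  v[t >= 900 & t <= ev[["glu_off"]]] <- 5   # rise of exactly the threshold
  v[t > ev[["glu_off"]]] <- 0
  tr <- ratio_trace("edge", t, v, kind = "excitation_ratio")
  expect_false(classify_dcd(tr, ev, smooth_s = 0, min_rise_frac = 0.25)$has_dcd)
  # one epsilon above the threshold flips the decision
  v2 <- v
  v2[t >= 900 & t <= ev[["glu_off"]]] <- 5 + 1e-9
  tr2 <- ratio_trace("edge2", t, v2, kind = "excitation_ratio")
  expect_true(classify_dcd(tr2, ev, smooth_s = 0, min_rise_frac = 0.25)$has_dcd)
})

test_that("tangent intersection reproduces exact piecewise-linear lags", {
  ev <- default_events()
  # flat plateau at 1.0, secondary slope 0.01 starting at t = 300 after glu
  pw <- make_tangent_trace(m1 = 0, v_on = 1.0, m2 = 0.01,
                           t_int = ev[["glu_on"]] + 300)
  est <- estimate_lag_dcd(pw$trace, ev)
  expect_equal(est$lag_dcd, 300, tolerance = 1e-6)

  # analytic 2x2 solve: y1 = 0.5 - 2e-4 t, y2 = 0.01 t - 2.5
  # intersection at t = 3 / 0.0102 = 294.1176... (counted from glu_on)
  glu_on <- ev[["glu_on"]]
  m1 <- -2e-4; m2 <- 0.01
  t_int_rel <- 3 / 0.0102
  pw2 <- make_tangent_trace(m1 = m1, v_on = 0.5, m2 = m2,
                            t_int = glu_on + t_int_rel)
  est2 <- estimate_lag_dcd(pw2$trace, ev)
  expect_equal(est2$lag_dcd, 294.1176470588, tolerance = 1e-4)
  # the fitted tangents coincide with the generating lines
  expect_equal(est2$tangent_first$slope, m1, tolerance = 1e-10)
  expect_equal(est2$tangent_secondary$slope, m2, tolerance = 1e-10)

  # parallel tangents are degenerate geometry
  flat1 <- make_tangent_trace(m1 = 0.001, v_on = 1, m2 = 0.01, t_int = 500)
  ph <- classify_dcd(flat1$trace, ev)
  ph$plateau_idx <- c(5L, 10L)  # force both fits onto the same line
  ph$rise_idx <- c(5L, 10L)
  ph$has_dcd <- TRUE
  expect_error(estimate_lag_dcd(flat1$trace, ev, phases = ph),
               "parallel|degenerate")
})

test_that("recovery index reproduces its defining arithmetic", {
  ev <- default_events()
  t <- seq(0, max(ev) + 100, by = 5)
  make_rec <- function(r_end) {
    # baseline 1 before glu, 3 at washout, linear to r_end at the horizon
    glu_on <- ev[["glu_on"]]; glu_off <- ev[["glu_off"]]
    horizon_end <- max(t[t < ev[["fccp_on"]]])
    v <- ifelse(t < glu_on, 1,
         ifelse(t <= glu_off, 1 + 2 * pmin(1, (t - glu_on) / 60),
         ifelse(t <= horizon_end,
                3 + (r_end - 3) * (t - glu_off) / (horizon_end - glu_off),
                r_end)))
    ratio_trace("r", t, v, kind = "excitation_ratio")
  }
  expect_equal(recovery_index(make_rec(1), ev)$index, 100)
  expect_equal(recovery_index(make_rec(3), ev)$index, 0)
  expect_equal(recovery_index(make_rec(2), ev)$index, 50)

  # affine invariance: a*x + b leaves X unchanged
  tr <- make_rec(1.7)
  x0 <- recovery_index(tr, ev)$index
  tr2 <- ratio_trace("r2", t, 3.1 * tr$values + 0.4, "excitation_ratio")
  expect_equal(recovery_index(tr2, ev)$index, x0)

  # no elevation at washout -> undefined, flagged
  flat <- ratio_trace("f", t, rep(1, length(t)), "excitation_ratio")
  ri <- recovery_index(flat, ev)
  expect_false(ri$defined)
  expect_true(is.na(ri$index))
})

test_that("sister-control normalization pins the control median at 1", {
  expect_equal(normalize_to_sister_control(150, c(100, 200, 300)), 0.75)
  ctrl <- c(3, 9, 1, 7, 5)
  expect_equal(median(normalize_to_sister_control(ctrl, ctrl)), 1)
  expect_error(normalize_to_sister_control(1, numeric(0)), "empty")
  expect_error(normalize_to_sister_control(1, c(-1, 0, 1)), "zero")
})

test_that("cohort summary matches independent quantile computation", {
  p <- small_cohort_params(seed = 6)
  res <- analyze_dcd_cohort(gen_calcium_cohort(p))
  s <- summarize_cohort(res)
  lags <- res$lag_dcd[res$has_dcd & !is.na(res$lag_dcd)]
  expect_equal(s$lag_median, unname(quantile(lags, 0.5, type = 7)))
  expect_equal(s$lag_q1, unname(quantile(lags, 0.25, type = 7)))
  expect_equal(s$lag_q3, unname(quantile(lags, 0.75, type = 7)))
  expect_equal(s$n, nrow(res))
  expect_equal(s$n_dcd, sum(res$has_dcd))

  # single cell: median equals its value
  one <- res[which(res$has_dcd)[1], ]
  s1 <- summarize_cohort(one)
  expect_equal(s1$lag_median, one$lag_dcd)
  # duplicated cohort: identical summary
  s2 <- summarize_cohort(rbind(res, res))
  expect_equal(s2$lag_median, s$lag_median)
  expect_equal(s2$recovery_median, s$recovery_median)
  expect_error(summarize_cohort(res[0, ]), "empty")
})

test_that("estimates degrade monotonically with noise but stay unbiased", {
  errs <- vapply(c(0.005, 0.02, 0.08), function(ns) {
    p <- small_cohort_params(seed = 11, noise_sd = ns)
    co <- gen_calcium_cohort(p)
    res <- analyze_dcd_cohort(co)
    m <- merge(res, co$truth, by = "cell_id")
    m <- m[m$has_dcd.x & m$has_dcd.y & !is.na(m$lag_dcd), ]
    sd(m$lag_dcd - m$lag_true)
  }, numeric(1))
  expect_true(all(diff(errs) > 0))
})
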