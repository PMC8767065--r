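# Trace I/O, ratio construction and the generic kinetic utilities.

test_that("wide and long trace tables load, validate, and round-trip", {
  wide <- data.frame(time = seq(0, 45, by = 5),
                     c1 = rnorm(10), c2 = rnorm(10), c3 = rnorm(10))
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(wide, f, row.names = FALSE)
  traces <- read_trace_table(f, layout = "wide")
  expect_length(traces, 3)
  expect_equal(vapply(traces, function(tr) length(tr$time), integer(1)),
               c(c1 = 10L, c2 = 10L, c3 = 10L))
  expect_equal(traces$c2$values, wide$c2)

  # minutes are converted to seconds
  tr_min <- read_trace_table(f, layout = "wide", time_units = "min")
  expect_equal(tr_min$c1$time, wide$time * 60)

  # duplicate timestamp rejected
  bad <- wide; bad$time[2] <- bad$time[1]
  write.csv(bad, f, row.names = FALSE)
  expect_error(read_trace_table(f, layout = "wide"), "monotone")

  # long-format round trip preserves the data
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_trace_table(traces, f2)
  back <- read_trace_table(f2, layout = "long")
  expect_equal(back$c1$values, traces$c1$values)
  expect_equal(back$c3$time, traces$c3$time)

  dup <- read.csv(f2); dup <- rbind(dup, dup[1, ])
  write.csv(dup, f2, row.names = FALSE)
  expect_error(read_trace_table(f2, layout = "long"), "duplicate")
})

test_that("excitation ratio is pointwise, validated, and scale-equivariant", {
  f340 <- fluor_trace("c1", c(0, 5), c(2, 2), "F340")
  f380 <- fluor_trace("c1", c(0, 5), c(1, 2), "F380")
  expect_equal(compute_excitation_ratio(f340, f380)$values, c(2, 1))
  expect_equal(compute_excitation_ratio(f340, f340)$values, c(1, 1))

  other_grid <- fluor_trace("c1", c(0, 6), c(1, 2), "F380")
  expect_error(compute_excitation_ratio(f340, other_grid), "alignment")
  zero <- fluor_trace("c1", c(0, 5), c(1, 0), "F380")
  expect_error(compute_excitation_ratio(f340, zero), "index 2")

  # scaling both channels by k leaves the ratio unchanged
  set.seed(4)
  a <- fluor_trace("c", 1:20, runif(20, 1, 3), "F340")
  b <- fluor_trace("c", 1:20, runif(20, 1, 3), "F380")
  k <- 7.3
  a2 <- fluor_trace("c", 1:20, k * a$values, "F340")
  b2 <- fluor_trace("c", 1:20, k * b$values, "F380")
  expect_equal(compute_excitation_ratio(a2, b2)$values,
               compute_excitation_ratio(a, b)$values)
})

test_that("F/F0 normalization divides by the baseline-window mean only", {
  tr <- fluor_trace("c", seq(0, 100, 5), rep(3.2, 21), "rh123")
  expect_equal(normalize_to_initial(tr, c(0, 30))$values, rep(1, 21))

  set.seed(9)
  v <- runif(21, 1, 4)
  tr2 <- fluor_trace("c", seq(0, 100, 5), v, "rh123")
  out <- normalize_to_initial(tr2, c(0, 30))
  expect_equal(out$values, v / mean(v[seq(0, 100, 5) <= 30]))
  expect_identical(out$kind, "f_over_f0")
  # scale invariance
  tr3 <- fluor_trace("c", seq(0, 100, 5), 5 * v, "rh123")
  expect_equal(normalize_to_initial(tr3, c(0, 30))$values, out$values)
  expect_error(normalize_to_initial(tr2, c(200, 300)), "empty")
})

test_that("moving-average smoothing attenuates a spike by the window size", {
  t <- seq(0, 100, 5)
  const <- ratio_trace("c", t, rep(2, length(t)), "f_over_f0")
  expect_equal(smooth_trace(const, 25)$values, rep(2, length(t)))
  expect_identical(smooth_trace(const, 0), const)
  expect_error(smooth_trace(const, -1), ">= 0")

  spike <- rep(0, length(t)); spike[10] <- 1
  sp <- ratio_trace("c", t, spike + 1, "f_over_f0")
  sm <- smooth_trace(sp, 20)  # +/-10 s -> 5 samples at dt = 5
  expect_equal(sm$values[10], 1 + 1 / 5)
  expect_equal(sm$values[12], 1 + 1 / 5)  # still inside the +/-10 s window
  expect_equal(sm$values[13], 1)          # first sample outside it
})

test_that("recovery half-time matches closed forms and flags non-recovery", {
  # linear decay 3 -> 1 over 200 s: half level 2 reached at 100 s
  t <- seq(0, 200, 5)
  lin <- ratio_trace("c", t, 3 - 2 * t / 200, "f_over_f0")
  ht <- recovery_halftime(lin, c(0, 200), baseline_level = 1, start_level = 3)
  expect_true(ht$crossed)
  expect_equal(ht$halftime, 100)

  # exponential decay tau = 100 s: half-time = tau * log(2) = 69.31 s
  t2 <- seq(0, 600, 1)
  ex <- ratio_trace("c", t2, 1 + 2 * exp(-t2 / 100), "f_over_f0")
  ht2 <- recovery_halftime(ex, c(0, 600), 1, 3)
  expect_equal(ht2$halftime, 100 * log(2), tolerance = 1e-3)

  # affine rescaling of signal and levels leaves the half-time unchanged
  ex2 <- ratio_trace("c", t2, 10 * (1 + 2 * exp(-t2 / 100)) + 4, "f_over_f0")
  ht3 <- recovery_halftime(ex2, c(0, 600), 10 * 1 + 4, 10 * 3 + 4)
  expect_equal(ht3$halftime, ht2$halftime)

  flat <- ratio_trace("c", t, rep(3, length(t)), "f_over_f0")
  expect_false(recovery_halftime(flat, c(0, 200), 1, 3)$crossed)
  expect_error(recovery_halftime(lin, c(-50, 100), 1, 3), "outside")
  expect_error(recovery_halftime(lin, c(0, 100), 3, 1), "exceed")
})

test_that("trace containers validate their invariants", {
  expect_error(fluor_trace("c", c(0, 5, 5), c(1, 2, 3)), "increasing")
  expect_error(fluor_trace("c", c(0, 5), c(1, NA)), "missing")
  expect_error(ratio_trace("c", c(0, 5), c(1, Inf)), "finite")
  expect_error(event_schedule(glu_on = 100, glu_off = 50), "increasing")
  ev <- default_events()
  f <- withr::local_tempfile(fileext = ".yaml")
  write_event_schedule(ev, f)
  expect_equal(unclass(read_event_schedule(f)), unclass(ev))
})
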