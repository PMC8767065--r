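# Fixtures built in code: piecewise-linear tangent traces (where the two
# segments ARE the tangents, so the analytic 2x2 line intersection is the
# oracle), simple kinetic traces, and the default event schedule.

default_events <- function() {
  event_schedule(glu_on = 120, glu_off = 1020, fccp_on = 1620,
                 iono_on = 1800)
}

# Trace = max(line1, line2) inside the glutamate window; flat baseline
# before glu_on; held constant after glu_off. Returns the trace plus the
# analytic intersection.
make_tangent_trace <- function(m1, v_on, m2, t_int,
                               glu_on = 120, glu_off = 1020, dt = 5,
                               cell_id = "pw") {
  t <- seq(0, glu_off + 100, by = dt)
  line1 <- function(tt) v_on + m1 * (tt - glu_on)
  # line2 passes through line1 at t_int with slope m2
  line2 <- function(tt) line1(t_int) + m2 * (tt - t_int)
  v <- ifelse(t < glu_on, v_on, pmax(line1(t), line2(t)))
  v[t > glu_off] <- v[max(which(t <= glu_off))]
  list(trace = ratio_trace(cell_id, t, v, kind = "excitation_ratio"),
       t_int = t_int, lag_true = t_int - glu_on)
}

# Monophasic control: rise at glu_on to a plateau, then exponential decay
# after washout.
make_monophasic_trace <- function(events = default_events(), dt = 5,
                                  base = 0.5, amp = 0.5, k = 0.004,
                                  cell_id = "mono") {
  glu_on <- events[["glu_on"]]; glu_off <- events[["glu_off"]]
  t <- seq(0, max(events) + 100, by = dt)
  v <- base + ifelse(t >= glu_on, amp * (1 - exp(-(t - glu_on) / 5)), 0)
  v_off <- base + amp * (1 - exp(-(glu_off - glu_on) / 5))
  post <- t > glu_off
  v[post] <- base + (v_off - base) * exp(-k * (t[post] - glu_off))
  ratio_trace(cell_id, t, v, kind = "excitation_ratio")
}

small_cohort_params <- function(...) {
  preset_cohort_params("cortical", n_cells = 40, ...)
}
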