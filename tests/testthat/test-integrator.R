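test_that("integer-crossing detection interpolates within the step", {
  expect_equal(detect_integer_crossing(0.99, 1.01, 0, 0.001), 5e-4)
  expect_true(is.na(detect_integer_crossing(0.50, 0.60, 1, 1.001)))
  # against a root-finding oracle on the linear interpolant
  tc <- detect_integer_crossing(0.98, 1.02, 10.0, 10.001)
  f <- function(t) 0.98 + (1.02 - 0.98) * (t - 10) / 0.001 - 1
  oracle <- uniroot(f, c(10, 10.001), tol = 1e-15)$root
  expect_equal(tc, oracle, tolerance = 1e-12)
  expect_error(detect_integer_crossing(0.2, 1.4, 0, 0.001), "reduce dt")
  expect_error(detect_integer_crossing(0.5, 0.4, 0, 0.001), "non-decreasing")
})

test_that("control-off runs are a metronome at the resting rate", {
  sim <- wk_simulate(wk_params(), duration = 40)
  # 1.1 cycles/s x 40 s beats, breaths every 3 s
  expect_equal(nrow(sim$beats), 44)
  expect_equal(length(sim$breath_onsets), 13)
  expect_lt(max(abs(sim$breath_onsets - 3 * (1:13))), 1e-9)
  expect_lt(max(abs(diff(sim$breath_onsets) - 3)), 1e-9)
  # RR intervals exactly 60/66 s
  rr <- diff(sim$beats$t_i)
  expect_lt(max(abs(rr - 60 / 66)), 1e-6)
  # beat times sit at integer phase up to interpolation tolerance
  expect_lt(max(abs(sim$beats$t_i * 1.1 - seq_len(44))), 1e-6)
})

test_that("total blood volume is conserved through flows and kicks", {
  p <- wk_params(r0 = -0.2)
  sim <- wk_simulate(p, duration = 40)
  ts <- sim$timeseries
  V <- p$C_a * ts$p_a + p$C_c * ts$p_c + p$C_v * ts$p_v
  expect_lt(max(abs(V - V[1])) / V[1], 1e-9)
})

test_that("arterial pressure decays monotonically between beats", {
  sim <- wk_simulate(wk_params(r0 = -0.2), duration = 40)
  ts <- sim$timeseries
  rises <- which(diff(ts$p_a) > 0)
  # any rise must be the kick itself (next row is the post-kick sample)
  not_kick <- rises[ts$event[rises + 1] != "beat_post"]
  expect_equal(sum(ts$p_a[not_kick] > ts$p_v[not_kick]), 0)
})

test_that("beat-free linear segments match the matrix-exponential solution", {
  # heart quiescent (r ~ 0), respiration modulation off: the pressure
  # subsystem is linear time-invariant with the diode open (p_v > p_c)
  p <- wk_params(r_bpm = 1e-6, p1 = 0)
  sim <- wk_simulate(p, duration = 1, transient = 0)
  A <- matrix(c(-p$Z_av / p$C_a, 0, p$Z_av / p$C_a,
                0, -p$Z_vc / p$C_c, p$Z_vc / p$C_c,
                p$Z_av / p$C_v, p$Z_vc / p$C_v,
                -(p$Z_av + p$Z_vc) / p$C_v),
              3, 3, byrow = TRUE)
  yT <- as.numeric(Matrix::expm(A) %*% c(90, 0, 9))
  fin <- sim$timeseries[nrow(sim$timeseries), ]
  expect_equal(c(fin$p_a, fin$p_c, fin$p_v), yT, tolerance = 1e-6)
  expect_equal(nrow(sim$beats), 0)
})

test_that("halving the step moves beat times by less than a millisecond", {
  p <- wk_params(r0 = -0.2)
  b1 <- wk_simulate(p, duration = 40, dt = 1e-3)$beats
  b2 <- wk_simulate(p, duration = 40, dt = 5e-4)$beats
  n <- min(nrow(b1), nrow(b2))
  expect_lt(max(abs(b1$t_i[seq_len(n)] - b2$t_i[seq_len(n)])), 1e-3)
})

test_that("identical inputs give identical output, to the byte", {
  p <- wk_params(r0 = -0.35, tau = 1.1)
  s1 <- wk_simulate(p, duration = 12)
  s2 <- wk_simulate(p, duration = 12)
  expect_identical(s1$beats, s2$beats)
  expect_identical(s1$timeseries, s2$timeseries)
  expect_identical(s1$breath_onsets, s2$breath_onsets)
})

test_that("phase-rate clamping engages under strong negative forcing", {
  sim <- wk_simulate(wk_params(r0 = -2), duration = 8, transient = 1)
  expect_gt(sim$clamp_events, 0)
  # the phase never decreases despite the clamped episodes
  expect_true(all(diff(sim$timeseries$phi) >= 0))
})

test_that("invalid settings are rejected", {
  expect_error(wk_simulate(wk_params(), dt = 0.01), "dt")
  expect_error(wk_simulate(wk_params(), duration = 5, transient = 6),
               "transient")
  expect_error(wk_simulate(wk_params(), init = c(p_a = 90)), "init")
})
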