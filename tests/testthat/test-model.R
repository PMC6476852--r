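test_that("intrathoracic pressure follows the respiratory phase", {
  p <- wk_params()
  expect_equal(intrathoracic_pressure(0, p), -3.6)     # onset: maximum
  expect_equal(intrathoracic_pressure(0.5, p), -6.6)   # peak inspiration
  # periodic with period 1; modulation off collapses to the baseline
  Phi <- seq(0, 1, by = 0.01)
  expect_equal(intrathoracic_pressure(Phi, p),
               intrathoracic_pressure(Phi + 7, p))
  expect_equal(intrathoracic_pressure(Phi, wk_params(p1 = 1e-12)),
               rep(-6.6, length(Phi)), tolerance = 1e-9)
  expect_true(all(intrathoracic_pressure(Phi, p) >= p$p0))
  expect_true(all(intrathoracic_pressure(Phi, p) <= p$p0 + 2 * p$p1))
})

test_that("phase effectiveness matches direct evaluation of its form", {
  expect_equal(phase_effectiveness(0), 1 / 1.008)
  expect_equal(phase_effectiveness(0.45), 0.55^3 / (0.2^3 + 0.55^3))
  # left limit at 1 is 0.55 (first term only)
  expect_equal(phase_effectiveness(1 - 1e-9), 0.55, tolerance = 1e-6)
  grid <- seq(0, 1 - 1e-4, length.out = 1e4)
  expect_equal(phase_effectiveness(grid), phase_eff_oracle(grid),
               tolerance = 1e-12)
  expect_true(all(is.finite(phase_effectiveness(grid))))
  expect_error(phase_effectiveness(1.2), "\\[0, 1\\)")
  expect_error(phase_effectiveness(-0.1), "\\[0, 1\\)")
})

test_that("neural forcing is a delayed decaying impulse per breath", {
  p <- wk_params(r0 = -0.2)
  # silent before the first kick; amplitude r0 at onset (Theta(0) = 1)
  expect_equal(neural_forcing(0.29, breath_onsets = 0, params = p), 0)
  expect_equal(neural_forcing(0.3, breath_onsets = 0, params = p), -0.2)
  # one e-folding after tau_n
  expect_equal(neural_forcing(0.3 + 0.3, breath_onsets = 0, params = p),
               -0.2 * exp(-1))
  # closed form for a single onset, through the decaying tail
  t <- seq(0.3, 2.5, by = 0.01)
  expect_equal(neural_forcing(t, breath_onsets = 0, params = p),
               p$r0 * exp(-(t - p$tau) / p$tau_n), tolerance = 1e-12)
  # kicks older than 10 tau_n are truncated to exactly zero
  expect_equal(neural_forcing(0.3 + 3.1, breath_onsets = 0, params = p), 0)
  # contributions from several breaths superpose
  on <- c(0, 3, 6)
  tt <- 6.4
  expect_equal(neural_forcing(tt, on, p),
               sum(p$r0 * exp(-(tt - on - p$tau) / p$tau_n) *
                     (tt - on - p$tau <= 3)), tolerance = 1e-12)
  expect_error(neural_forcing(1, c(3, 0), p), "sorted")
})

test_that("continuous dynamics obey the diode and conserve volume rate", {
  p <- wk_params()
  # zero gradients and closed diode freeze all pressures
  d <- continuous_rhs(list(t = 0, p_a = 50, p_c = 60, p_v = 50,
                           phi = 0.2, Phi = 0.1), p)
  expect_equal(unname(d[c("p_a", "p_c", "p_v")]), c(0, 0, 0))
  # diode closed: no filling even with arterial runoff active
  d <- continuous_rhs(list(t = 0, p_a = 120, p_c = 10, p_v = 8,
                           phi = 0.2, Phi = 0.1), p)
  expect_equal(unname(d["p_c"]), 0)
  expect_lt(d[["p_a"]], 0)
  # control off: the phase advances at the resting rate
  expect_equal(unname(d["phi"]), 1.1)
  expect_equal(unname(d["Phi"]), 1 / 3)
  # volume-rate identity across random states
  for (k in 1:20) {
    st <- list(t = k, p_a = 40 + 7 * k, p_c = -5 + k, p_v = 3 + 0.2 * k,
               phi = 0.1 * k, Phi = 0.03 * k)
    d <- continuous_rhs(st, p, breath_onsets = c(0, 3))
    expect_equal(p$C_a * d[["p_a"]] + p$C_c * d[["p_c"]] + p$C_v * d[["p_v"]],
                 0, tolerance = 1e-12)
  }
})

test_that("heartbeat transfer moves volume without creating it", {
  # unit-time impulse: dV = Z_ca * (p_c - p_I) per mmHg of gradient
  p1 <- wk_params(kick_unit_time = 1)
  st <- list(p_a = 120, p_c = -3, p_v = 8, phi = 1, Phi = 0) # p_I = -3.6
  out <- heartbeat_transfer(st, p1)
  expect_equal(out$dV, 99.6)
  expect_equal(out$state$p_a - st$p_a, 99.6 / 1.6)
  expect_equal(out$state$p_c - st$p_c, -99.6 / 4.3)
  expect_equal(out$state$p_v, st$p_v)
  # equal-and-opposite volume: C_a dp_a + C_c dp_c = 0
  expect_equal(p1$C_a * (out$state$p_a - st$p_a) +
                 p1$C_c * (out$state$p_c - st$p_c), 0, tolerance = 1e-12)
  # zero gradient: nothing happens
  st0 <- list(p_a = 120, p_c = -3.6, p_v = 8, phi = 1, Phi = 0)
  out0 <- heartbeat_transfer(st0, p1)
  expect_equal(out0$dV, 0)
  expect_equal(out0$state$p_a, st0$p_a)
  # negative gradient is applied as written (no ejection valve)
  stn <- list(p_a = 120, p_c = -5, p_v = 8, phi = 1, Phi = 0)
  expect_lt(heartbeat_transfer(stn, p1)$dV, 0)
  # default 50-ms impulse scales the same gradient down
  expect_equal(heartbeat_transfer(st, wk_params())$dV, 0.05 * 99.6)
})
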