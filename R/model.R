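#' Intrathoracic pressure as a function of respiratory phase
#'
#' `p_I(Phi) = p0 + p1 * (1 + cos(2 pi Phi))`.  The pressure is maximal
#' (`p0 + 2 p1`) at integer phase — the onset of inspiration — and minimal
#' (`p0`) at half-integer phase (peak inspiration), with period 1 in `Phi`.
#'
#' @param Phi Respiratory phase in cycles (any real; the function is
#'   periodic).
#' @param params A [wk_params()] object.
#' @return Pressure in mmHg, vectorised over `Phi`.
#' @examples
#' intrathoracic_pressure(0, wk_params())    # -3.6
#' intrathoracic_pressure(0.5, wk_params())  # -6.6
#' @export
intrathoracic_pressure <- function(Phi, params = wk_params()) {
  stopifnot(inherits(params, "wk_params"))
  params$p0 + params$p1 * (1 + cos(2 * pi * Phi))
}

#' Phase-effectiveness of a neural stimulus
#'
#' Gain of a neural impulse as a function of the cardiac phase at which it
#' arrives, in the semi-empirical form
#' `F(phi) = phi^1.3 (phi - 0.45) + (1 - phi)^3 / (0.2^3 + (1 - phi)^3)`.
#' Early-cycle stimuli act with near-unit gain; the sign change of the first
#' term around the vulnerable phase reproduces the "vagal paradox" in which
#' the same stimulus can shorten rather than lengthen the cycle.
#'
#' @param phi Cardiac phase folded to `[0, 1)` (callers fold; exact 1 folds
#'   to 0).
#' @return Dimensionless gain, vectorised over `phi`.
#' @examples
#' phase_effectiveness(0)     # ~0.9921
#' phase_effectiveness(0.45)  # ~0.9541
#' @export
phase_effectiveness <- function(phi) {
  if (any(phi < 0 | phi >= 1)) {
    stop("`phi` must be folded to [0, 1)", call. = FALSE)
  }
  .wk_phase_eff_cpp(as.numeric(phi))
}

#' Respiration-gated neural forcing
#'
#' Sum over breaths of a decaying impulse
#' `f(u) = r0 * Theta(u) * exp(-u / tau_n)` evaluated at
#' `u = t - t_j - tau`, i.e. each inspiration onset `t_j` launches a spike
#' of amplitude `r0` after the control delay `tau`, which then decays with
#' time constant `tau_n`.  `Theta(0) = 1` (the impulse is active at its
#' onset instant).  Contributions older than `10 * tau_n` are truncated.
#'
#' @param t Time(s) at which to evaluate the forcing, s.
#' @param breath_onsets Sorted ascending inspiration-onset times `t_j`, s.
#' @param params A [wk_params()] object (uses `r0`, `tau`, `tau_n`).
#' @return Phase-rate contribution in cycles/s, vectorised over `t`.
#' @examples
#' p <- wk_params(r0 = -0.2)
#' neural_forcing(0.1, breath_onsets = 0, params = p)  # 0: before the kick
#' neural_forcing(0.3, breath_onsets = 0, params = p)  # -0.2: kick onset
#' @export
neural_forcing <- function(t, breath_onsets, params = wk_params()) {
  stopifnot(inherits(params, "wk_params"))
  if (is.unsorted(breath_onsets)) {
    stop("`breath_onsets` must be sorted ascending", call. = FALSE)
  }
  vapply(t, function(tt) {
    age <- tt - breath_onsets - params$tau
    keep <- age >= 0 & age <= 10 * params$tau_n
    sum(params$r0 * exp(-age[keep] / params$tau_n))
  }, numeric(1))
}

#' Continuous-time right-hand side of the model
#'
#' Flow terms between the three compartments (the ejection impulse excluded),
#' the cardiac phase velocity under neural forcing, and the constant
#' respiratory phase velocity:
#' \itemize{
#'   \item `dp_a/dt = -Z_av (p_a - p_v) / C_a` — Windkessel runoff;
#'   \item `dp_c/dt = max(Z_vc (p_v - p_c), 0) / C_c` — diode-gated filling;
#'   \item `dp_v/dt = (Z_av (p_a - p_v) - max(Z_vc (p_v - p_c), 0)) / C_v`;
#'   \item `dphi/dt = max(r + f(t) F(phi mod 1), 0)` — rate clamped at 0 so
#'     the phase never runs backwards;
#'   \item `dPhi/dt = R`.
#' }
#' The flow terms conserve total volume:
#' `C_a dp_a + C_c dp_c + C_v dp_v = 0` exactly.
#'
#' @param state Named list or vector with `t`, `p_a`, `p_c`, `p_v`, `phi`,
#'   `Phi`.
#' @param params A [wk_params()] object.
#' @param breath_onsets Inspiration-onset times for the neural forcing
#'   (default none).
#' @return Named numeric vector of derivatives
#'   `(p_a, p_c, p_v, phi, Phi)`.
#' @export
continuous_rhs <- function(state, params = wk_params(),
                           breath_onsets = numeric(0)) {
  stopifnot(inherits(params, "wk_params"))
  s <- as.list(state)
  p_av <- s$p_a - s$p_v
  q_in <- max(params$Z_vc * (s$p_v - s$p_c), 0)
  f <- neural_forcing(s$t, breath_onsets, params)
  dphi <- max(params$r + f * phase_effectiveness(s$phi %% 1), 0)
  c(p_a = -params$Z_av * p_av / params$C_a,
    p_c = q_in / params$C_c,
    p_v = (params$Z_av * p_av - q_in) / params$C_v,
    phi = dphi,
    Phi = params$R)
}

#' Instantaneous heartbeat volume transfer
#'
#' Applies the ejection impulse at a beat: a volume
#' `dV = kick_unit_time * Z_ca * (p_c - p_I(Phi))` moves from the
#' cardiopulmonary to the arterial compartment, so
#' `p_a <- p_a + dV / C_a` and `p_c <- p_c - dV / C_c`; `p_v` is untouched
#' and total volume `C_a p_a + C_c p_c + C_v p_v` is invariant to round-off.
#' A negative gradient (`p_c < p_I`) yields a negative `dV`, applied as
#' written: the ejection impulse has no valve.
#'
#' @param state Named list or vector with `p_a`, `p_c`, `p_v`, `Phi` (and
#'   optionally `t`, `phi`, passed through).
#' @param params A [wk_params()] object.
#' @return A list with `state` (updated) and `dV` (ejected volume, ml).
#' @examples
#' st <- list(p_a = 120, p_c = -3, p_v = 8, phi = 1, Phi = 0)
#' heartbeat_transfer(st, wk_params(kick_unit_time = 1))$dV  # 99.6 ml
#' @export
heartbeat_transfer <- function(state, params = wk_params()) {
  stopifnot(inherits(params, "wk_params"))
  s <- as.list(state)
  p_I <- intrathoracic_pressure(s$Phi, params)
  dV <- params$kick_unit_time * params$Z_ca * (s$p_c - p_I)
  s$p_a <- s$p_a + dV / params$C_a
  s$p_c <- s$p_c - dV / params$C_c
  list(state = s, dV = dV)
}
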