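#' Model parameters for the kicked-Windkessel system
#'
#' Constructs the full parameter set of the three-compartment
#' cardiorespiratory model: compliances and conductances of the arterial,
#' cardiopulmonary and venous compartments, the intrathoracic pressure
#' baseline and respiratory modulation amplitude, the resting cardiac and
#' respiratory rates, and the three parameters of the respiration-gated
#' neural control of heart rate (amplitude `r0`, delay `tau`, decay time
#' `tau_n`).
#'
#' Rates are supplied in beats/breaths per minute (`r_bpm`, `R_bpm`) and
#' stored internally in cycles per second (`r`, `R`).  The heartbeat is an
#' instantaneous volume transfer `dV = kick_unit_time * Z_ca * (p_c - p_I)`
#' from the cardiopulmonary to the arterial compartment; `kick_unit_time`
#' (seconds) is the effective duration of the ejection impulse and defaults
#' to 0.05 s, which places the operating point (mean arterial pressure
#' ~120 mmHg, stroke volume ~110 ml, venous pressure slightly above the
#' physiological level) where a resting human sits.
#'
#' The neural-control amplitude `r0` defaults to 0 (control off): the
#' buffering analysis defines its reference state this way, and sweep
#' functions require an explicit amplitude.
#'
#' @param C_a Systemic arterial compliance, ml/mmHg.
#' @param C_v Systemic venous compliance, ml/mmHg.
#' @param C_c Effective cardiopulmonary compliance, ml/mmHg.
#' @param Z_vc Venous-to-cardiopulmonary (ventricular filling) conductance,
#'   ml/(s mmHg).
#' @param Z_av Arterial outflow conductance (reciprocal of total peripheral
#'   resistance), ml/(s mmHg).
#' @param Z_ca Effective cardiopulmonary outflow conductance scaling the
#'   ejection impulse, ml/(s mmHg).
#' @param p0 Intrathoracic baseline pressure, mmHg.
#' @param p1 Intrathoracic respiratory modulation amplitude, mmHg.
#' @param r_bpm Resting heart rate, beats per minute.
#' @param r0 Neural-control amplitude, cycles/s (sign sets the direction of
#'   the phase kick; negative values slow the heart).
#' @param tau Neural-control delay after inspiration onset, s.
#' @param tau_n Neural-control decay time constant, s.
#' @param R_bpm Resting respiratory rate, breaths per minute.
#' @param kick_unit_time Effective duration of the ejection impulse, s.
#'
#' @return An object of class `wk_params`: a named list with the fields
#'   above plus the converted rates `r` and `R` in cycles/s.
#' @examples
#' p <- wk_params()
#' p$r # 1.1 cycles/s
#' wk_params(tau = 1.7, r0 = -0.2)
#' @export
wk_params <- function(C_a = 1.6, C_v = 100, C_c = 4.3,
                      Z_vc = 200, Z_av = 1.1, Z_ca = 166,
                      p0 = -6.6, p1 = 1.5,
                      r_bpm = 66, r0 = 0, tau = 0.3, tau_n = 0.3,
                      R_bpm = 20, kick_unit_time = 0.05) {
  p <- list(
    C_a = C_a, C_v = C_v, C_c = C_c,
    Z_vc = Z_vc, Z_av = Z_av, Z_ca = Z_ca,
    p0 = p0, p1 = p1,
    r_bpm = r_bpm, r0 = r0, tau = tau, tau_n = tau_n,
    R_bpm = R_bpm, kick_unit_time = kick_unit_time,
    r = r_bpm / 60, R = R_bpm / 60
  )
  validate_wk_params(p)
  structure(p, class = "wk_params")
}

validate_wk_params <- function(p) {
  must_pos <- c("C_a", "C_v", "C_c", "Z_vc", "Z_av", "Z_ca",
                "tau_n", "r_bpm", "R_bpm", "kick_unit_time")
  for (key in must_pos) {
    v <- p[[key]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      stop("parameter `", key, "` must be a single positive finite number",
           call. = FALSE)
    }
  }
  for (key in c("p0", "p1", "r0", "tau")) {
    v <- p[[key]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      stop("parameter `", key, "` must be a single finite number",
           call. = FALSE)
    }
  }
  if (p$tau < 0) stop("parameter `tau` must be >= 0", call. = FALSE)
  if (p$p1 < 0) stop("parameter `p1` must be >= 0", call. = FALSE)
  invisible(p)
}

#' @export
print.wk_params <- function(x, ...) {
  cat("<wk_params> kicked-Windkessel parameter set\n")
  cat(sprintf("  compliances  C_a=%g C_c=%g C_v=%g ml/mmHg\n",
              x$C_a, x$C_c, x$C_v))
  cat(sprintf("  conductances Z_vc=%g Z_av=%g Z_ca=%g ml/(s mmHg)\n",
              x$Z_vc, x$Z_av, x$Z_ca))
  cat(sprintf("  intrathoracic p0=%g p1=%g mmHg\n", x$p0, x$p1))
  cat(sprintf("  rates r=%g BPM (%.4g cyc/s)  R=%g BPM (%.4g cyc/s)\n",
              x$r_bpm, x$r, x$R_bpm, x$R))
  cat(sprintf("  control r0=%g cyc/s  tau=%g s  tau_n=%g s\n",
              x$r0, x$tau, x$tau_n))
  cat(sprintf("  ejection impulse kick_unit_time=%g s\n", x$kick_unit_time))
  invisible(x)
}

#' Modify a parameter set
#'
#' Returns a copy of `params` with the named fields replaced and all
#' invariants re-checked.  Rates are modified through `r_bpm` / `R_bpm`.
#'
#' @param params A [wk_params()] object.
#' @param ... Named fields to override, e.g. `tau = 1.7`, `r0 = -0.2`.
#' @return A new `wk_params` object.
#' @examples
#' wk_params() |> wk_modify(r0 = -0.2, tau = 1.0)
#' @export
wk_modify <- function(params, ...) {
  stopifnot(inherits(params, "wk_params"))
  dots <- list(...)
  allowed <- setdiff(names(unclass(params)), c("r", "R"))
  bad <- setdiff(names(dots), allowed)
  if (length(bad) > 0) {
    stop("unknown parameter field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  p <- unclass(params)
  p[names(dots)] <- dots
  do.call(wk_params, p[allowed])
}

#' Read / write a parameter configuration file
#'
#' Parameter sets round-trip through a flat YAML mapping whose keys are the
#' constructor arguments of [wk_params()] (`C_a`, `C_v`, `C_c`, `Z_vc`,
#' `Z_av`, `Z_ca`, `p0`, `p1`, `r_bpm`, `r0`, `tau`, `tau_n`, `R_bpm`,
#' `kick_unit_time`).  Keys absent from the file keep their defaults; an
#' empty file yields the default parameter set; unknown keys are an error.
#' The packaged default configuration is at
#' `system.file("extdata", "default_params.yaml", package = "windkick")`.
#'
#' @param path Path of the YAML file.
#' @return `read_wk_params()` returns a `wk_params` object;
#'   `write_wk_params()` returns `path` invisibly.
#' @examples
#' cfg <- system.file("extdata", "default_params.yaml", package = "windkick")
#' read_wk_params(cfg)
#' @export
read_wk_params <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config must be a flat key-value mapping",
                          call. = FALSE)
  allowed <- names(formals(wk_params))
  bad <- setdiff(names(raw), allowed)
  if (length(bad) > 0) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  do.call(wk_params, raw)
}

#' @rdname read_wk_params
#' @param params A [wk_params()] object to serialise.
#' @export
write_wk_params <- function(params, path) {
  stopifnot(inherits(params, "wk_params"))
  keys <- names(formals(wk_params))
  yaml::write_yaml(unclass(params)[keys], path)
  invisible(path)
}
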