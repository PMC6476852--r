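#' Simulate the kicked-Windkessel model
#'
#' Advances the coupled pressure/phase system with a fixed-step
#' fourth-order integrator.  Integer crossings of the cardiac phase are
#' located by linear interpolation inside the step; the step is split
#' there, the instantaneous ejection impulse applied, and integration
#' resumed.  Integer crossings of the respiratory phase are recorded as
#' inspiration onsets and schedule a neural impulse at delay `tau`.  The
#' run is fully deterministic: identical inputs give bit-identical output.
#'
#' The returned time series contains, besides the regular sampling grid,
#' two extra rows per beat holding the pre-kick and post-kick state at the
#' exact beat time (flagged in `event`), so that per-beat extrema and
#' trapezoidal averages resolve the pressure jump exactly.
#'
#' @param params A [wk_params()] object.
#' @param duration Total simulated time, s.
#' @param dt Fixed integration step, s (must be in `(0, 0.005]`).
#' @param transient Initial window, s, flagged for later discarding by the
#'   beat statistics (stored in the result; the full trajectory is kept).
#' @param init Named numeric vector of initial state
#'   `(p_a, p_c, p_v, phi, Phi)`.  The default places the operating point
#'   in the physiological range; no beat is fired at `t = 0` even though
#'   `phi = 0` is an integer — the first beat occurs at the first crossing
#'   of `phi = 1`.
#' @param record_stride Keep every `record_stride`-th grid sample (event
#'   rows are always kept).
#' @return An object of class `wk_sim` with elements:
#' \describe{
#'   \item{timeseries}{tibble with `t`, `p_a`, `p_c`, `p_v`, `p_I`, `phi`,
#'     `Phi`, `event` (`"none"`, `"beat_pre"`, `"beat_post"`).}
#'   \item{beats}{tibble with `i`, `t_i`, `dV` — beat times and ejected
#'     volumes (ml).  Per-beat pressures come from [extract_beats()].}
#'   \item{breath_onsets}{inspiration-onset times, s.}
#'   \item{clamp_events}{number of integration steps on which the cardiac
#'     phase rate was clamped at zero.}
#'   \item{negative_ejections}{number of beats with `p_c < p_I`, i.e. a
#'     negative ejected volume.}
#'   \item{params, duration, dt, transient}{the inputs.}
#' }
#' @examples
#' sim <- wk_simulate(wk_params(), duration = 5)
#' sim$beats
#' @export
wk_simulate <- function(params = wk_params(), duration = 40, dt = 1e-3,
                        transient = 10,
                        init = c(p_a = 90, p_c = 0, p_v = 9,
                                 phi = 0, Phi = 0),
                        record_stride = 1L) {
  stopifnot(inherits(params, "wk_params"))
  if (!(dt > 0 && dt <= 0.005)) stop("`dt` must be in (0, 0.005]",
                                     call. = FALSE)
  if (!(duration > transient && transient >= 0)) {
    stop("need duration > transient >= 0", call. = FALSE)
  }
  need <- c("p_a", "p_c", "p_v", "phi", "Phi")
  if (!all(need %in% names(init))) {
    stop("`init` must name ", paste(need, collapse = ", "), call. = FALSE)
  }
  raw <- .wk_simulate_cpp(unclass(params), duration, dt,
                          as.numeric(init[need]), as.integer(record_stride))
  ts <- tibble::tibble(
    t = raw$t,
    p_a = raw$p_a, p_c = raw$p_c, p_v = raw$p_v,
    p_I = intrathoracic_pressure(raw$Phi, params),
    phi = raw$phi, Phi = raw$Phi,
    event = c("none", "beat_pre", "beat_post")[raw$event + 1L]
  )
  beats <- tibble::tibble(
    i = seq_along(raw$beat_times),
    t_i = raw$beat_times,
    dV = raw$ejected_volumes
  )
  structure(
    list(timeseries = ts, beats = beats,
         breath_onsets = raw$breath_onsets,
         clamp_events = raw$clamp_events,
         negative_ejections = raw$negative_ejections,
         params = params, duration = duration, dt = dt,
         transient = transient),
    class = "wk_sim"
  )
}

#' @export
print.wk_sim <- function(x, ...) {
  cat(sprintf(
    "<wk_sim> %g s at dt=%g s: %d beats, %d breaths, %d clamped steps, %d negative ejections\n",
    x$duration, x$dt, nrow(x$beats), length(x$breath_onsets),
    x$clamp_events, x$negative_ejections))
  ba <- dplyr::filter(x$timeseries, t >= x$transient)
  cat(sprintf("  p_a in [%.1f, %.1f] mmHg after the %g-s transient\n",
              min(ba$p_a), max(ba$p_a), x$transient))
  invisible(x)
}

#' Detect an integer crossing of a monotone phase within one step
#'
#' Given the phase at both ends of a step, returns the
#' linearly-interpolated time at which the phase crosses the next integer,
#' or `NA` if no integer lies in `(phase_before, phase_after]`.  At most
#' one crossing per step is permitted; a phase advancing a full cycle or
#' more within one step signals that the step size is too large.
#'
#' @param phase_before,phase_after Phase at the start and end of the step
#'   (`phase_after >= phase_before`).
#' @param t_before,t_after Times bounding the step, s.
#' @return Crossing time, s, or `NA_real_`.
#' @examples
#' detect_integer_crossing(0.99, 1.01, 0, 0.001) # 5e-4
#' @export
detect_integer_crossing <- function(phase_before, phase_after,
                                    t_before, t_after) {
  if (phase_after < phase_before) {
    stop("phase must be non-decreasing over the step", call. = FALSE)
  }
  if (phase_after - phase_before >= 1) {
    stop("phase advanced >= 1 cycle within one step; reduce dt",
         call. = FALSE)
  }
  if (floor(phase_after) <= floor(phase_before)) return(NA_real_)
  i <- floor(phase_after)
  t_before + (t_after - t_before) * (i - phase_before) /
    (phase_after - phase_before)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a simulation: the per-beat table
#'
#' Returns the per-beat record table of [extract_beats()] — one row per
#' complete inter-beat interval after the transient, with RR interval and
#' systolic/diastolic/mean pressures.
#'
#' @param x A `wk_sim` object.
#' @param ... Unused.
#' @return A tibble; see [extract_beats()].
#' @export
tidy.wk_sim <- function(x, ...) extract_beats(x)

#' Glance at a simulation: one-row summary
#'
#' @param x A `wk_sim` object.
#' @param ... Unused.
#' @return A one-row tibble with beat/breath counts, mean heart rate (BPM),
#'   mean pressures and per-beat standard deviations after the transient.
#' @export
glance.wk_sim <- function(x, ...) {
  b <- extract_beats(x)
  tibble::tibble(
    n_beats = nrow(x$beats),
    n_breaths = length(x$breath_onsets),
    mean_hr_bpm = 60 / mean(b$RR),
    mean_SAP = mean(b$SAP), mean_DAP = mean(b$DAP), mean_MAP = mean(b$MAP),
    sd_SAP = beat_series_std(b, "SAP"),
    sd_DAP = beat_series_std(b, "DAP"),
    sd_MAP = beat_series_std(b, "MAP"),
    sd_RR = beat_series_std(b, "RR"),
    clamp_events = x$clamp_events,
    negative_ejections = x$negative_ejections
  )
}

#' Plot the pressure and phase traces of a simulation
#'
#' Stacked panels with the arterial, cardiopulmonary and venous pressures,
#' the intrathoracic pressure, and the two phases folded to one cycle.
#'
#' @param object A `wk_sim` object.
#' @param from,to Time window to show, s (defaults to the full run).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.wk_sim <- function(object, from = NULL, to = NULL, ...) {
  ts <- object$timeseries
  if (!is.null(from)) ts <- dplyr::filter(ts, t >= from)
  if (!is.null(to)) ts <- dplyr::filter(ts, t <= to)
  long <- ts |>
    dplyr::mutate(phi = phi %% 1, Phi = Phi %% 1) |>
    tidyr::pivot_longer(c("p_a", "p_c", "p_v", "p_I", "phi", "Phi"),
                        names_to = "variable", values_to = "value") |>
    dplyr::mutate(variable = factor(variable,
                                    levels = c("p_a", "p_c", "p_v",
                                               "p_I", "phi", "Phi")))
  ggplot2::ggplot(long, ggplot2::aes(t, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$variable),
                        scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
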