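#' Reference fluctuation magnitudes with the neural control off
#'
#' Runs the model with the control amplitude forced to zero — respiration
#' still modulates the ejection through the intrathoracic pressure — and
#' returns the per-beat standard deviations of SAP, DAP and MAP.  These are
#' the denominators of the relative fluctuation magnitudes: with `p1 > 0`
#' all three are strictly positive, and `p1 = 0` is rejected because a
#' zero-fluctuation reference would make the ratios undefined.
#'
#' @param params A [wk_params()] object (its `r0` is ignored; the reference
#'   forces `r0 = 0`).
#' @param duration,dt,transient Simulation settings as in [wk_simulate()].
#' @return Named numeric vector `c(SAP =, DAP =, MAP =)` in mmHg.
#' @examples
#' reference_fluctuations(wk_params(), duration = 20)
#' @export
reference_fluctuations <- function(params = wk_params(), duration = 40,
                                   dt = 1e-3, transient = 10) {
  stopifnot(inherits(params, "wk_params"))
  if (params$p1 <= 0) {
    stop("reference run is degenerate: `p1` must be > 0 so respiration ",
         "generates fluctuations", call. = FALSE)
  }
  sim <- wk_simulate(wk_modify(params, r0 = 0), duration = duration,
                     dt = dt, transient = transient)
  b <- extract_beats(sim)
  c(SAP = beat_series_std(b, "SAP"),
    DAP = beat_series_std(b, "DAP"),
    MAP = beat_series_std(b, "MAP"))
}

#' Relative fluctuation magnitude of a controlled run
#'
#' Runs the model at the given parameters (control on) and expresses the
#' per-beat standard deviations of SAP, DAP and MAP as percentages of the
#' control-off reference.  Values below 100 mean the respiratory
#' fluctuations of that variable are buffered by the heart-rate control;
#' values above 100 mean paradoxical enhancement.
#'
#' @param params A [wk_params()] object (with the control of interest set).
#' @param reference Named vector from [reference_fluctuations()].
#' @param duration,dt,transient Simulation settings as in [wk_simulate()].
#' @return Named numeric vector `c(rel_SAP =, rel_DAP =, rel_MAP =)` in
#'   percent.
#' @export
relative_magnitude <- function(params, reference, duration = 40,
                               dt = 1e-3, transient = 10) {
  stopifnot(inherits(params, "wk_params"))
  if (!all(c("SAP", "DAP", "MAP") %in% names(reference)) ||
      any(reference[c("SAP", "DAP", "MAP")] <= 0)) {
    stop("`reference` must hold positive SAP, DAP and MAP stds",
         call. = FALSE)
  }
  sim <- wk_simulate(params, duration = duration, dt = dt,
                     transient = transient)
  b <- extract_beats(sim)
  c(rel_SAP = 100 * beat_series_std(b, "SAP") / reference[["SAP"]],
    rel_DAP = 100 * beat_series_std(b, "DAP") / reference[["DAP"]],
    rel_MAP = 100 * beat_series_std(b, "MAP") / reference[["MAP"]])
}

#' Sweep the control delay or amplitude
#'
#' Computes the relative fluctuation magnitudes of SAP, DAP and MAP over a
#' grid of the neural-control delay `tau` or amplitude `r0`, against a
#' single shared control-off reference (the reference depends only on the
#' non-control parameters).  A failed run at a grid point is recorded as
#' `NA` with a warning, never silently dropped.
#'
#' @param params Base [wk_params()] object; for a `tau` sweep its `r0` is
#'   the fixed amplitude (must be non-zero to be informative), for an `r0`
#'   sweep its `tau` is the fixed delay.
#' @param name `"tau"` or `"r0"`.
#' @param grid Strictly increasing parameter values: delays in s
#'   (non-negative, at most 1.2 respiratory periods) or amplitudes in
#'   cycles/s (within `[-1, 1]`).
#' @param duration,dt,transient Simulation settings per grid point; the
#'   defaults (40-s runs, 10-s transient) leave about 33 beats of
#'   statistics per point.
#' @return An object of class `wk_sweep`: a list with `parameter`, `tbl`
#'   (tibble: `value`, `rel_SAP`, `rel_DAP`, `rel_MAP`), `reference_stds`,
#'   `params` and the settings.
#' @examples
#' sw <- sweep_parameter(wk_params(r0 = -0.2), "tau",
#'                       grid = seq(0, 3, by = 0.5), duration = 20)
#' tidy(sw)
#' @export
sweep_parameter <- function(params, name = c("tau", "r0"), grid,
                            duration = 40, dt = 1e-3, transient = 10) {
  stopifnot(inherits(params, "wk_params"))
  name <- match.arg(name)
  if (length(grid) < 1 || is.unsorted(grid, strictly = TRUE)) {
    stop("`grid` must be strictly increasing", call. = FALSE)
  }
  if (name == "tau" &&
      (min(grid) < 0 || max(grid) > 1.2 / params$R)) {
    stop("tau grid outside [0, 1.2 respiratory periods]", call. = FALSE)
  }
  if (name == "r0" && (min(grid) < -1 || max(grid) > 1)) {
    stop("r0 grid outside [-1, 1] cycles/s", call. = FALSE)
  }
  reference <- reference_fluctuations(params, duration = duration, dt = dt,
                                      transient = transient)
  rows <- purrr::map(grid, function(v) {
    p <- if (name == "tau") wk_modify(params, tau = v) else
      wk_modify(params, r0 = v)
    tryCatch(
      relative_magnitude(p, reference, duration = duration, dt = dt,
                         transient = transient),
      error = function(e) {
        warning("run at ", name, " = ", v, " failed: ",
                conditionMessage(e), call. = FALSE)
        c(rel_SAP = NA_real_, rel_DAP = NA_real_, rel_MAP = NA_real_)
      })
  })
  tbl <- tibble::tibble(
    value = grid,
    rel_SAP = purrr::map_dbl(rows, "rel_SAP"),
    rel_DAP = purrr::map_dbl(rows, "rel_DAP"),
    rel_MAP = purrr::map_dbl(rows, "rel_MAP")
  )
  structure(
    list(parameter = name, tbl = tbl, reference_stds = reference,
         params = params, duration = duration, dt = dt,
         transient = transient),
    class = "wk_sweep"
  )
}

#' @export
print.wk_sweep <- function(x, ...) {
  cat(sprintf("<wk_sweep> over %s: %d grid points in [%g, %g]\n",
              x$parameter, nrow(x$tbl), min(x$tbl$value), max(x$tbl$value)))
  cat(sprintf("  reference stds (mmHg): SAP=%.3f DAP=%.3f MAP=%.3f\n",
              x$reference_stds[["SAP"]], x$reference_stds[["DAP"]],
              x$reference_stds[["MAP"]]))
  print(x$tbl, n = 6)
  invisible(x)
}

#' @rdname sweep_parameter
#' @param x A `wk_sweep` object.
#' @param ... Unused.
#' @export
tidy.wk_sweep <- function(x, ...) x$tbl

#' @rdname sweep_parameter
#' @export
glance.wk_sweep <- function(x, ...) {
  tibble::tibble(
    parameter = x$parameter,
    n_points = nrow(x$tbl),
    ref_sd_SAP = x$reference_stds[["SAP"]],
    ref_sd_DAP = x$reference_stds[["DAP"]],
    ref_sd_MAP = x$reference_stds[["MAP"]],
    min_rel_MAP = min(x$tbl$rel_MAP, na.rm = TRUE),
    max_rel_SAP = max(x$tbl$rel_SAP, na.rm = TRUE)
  )
}

#' Effective-control intervals of a sweep
#'
#' Maximal contiguous parameter ranges over which the relative fluctuation
#' magnitude of one variable stays below 100% (effective buffering).
#' Interior endpoints are refined by linear interpolation of the relative
#' curve across the 100% level; an interval reaching the edge of the grid
#' keeps the grid endpoint.  The complement of these intervals is the
#' regime of ineffective control, including paradoxical enhancement where
#' the curve exceeds 100%.
#'
#' @param sweep A [sweep_parameter()] result (must be complete — no `NA` —
#'   for the chosen variable).
#' @param variable One of `"MAP"`, `"SAP"`, `"DAP"`.
#' @return A tibble with columns `variable`, `lower`, `upper`; zero rows
#'   when no grid point is below 100%.
#' @examples
#' sw <- list(parameter = "tau",
#'            tbl = tibble::tibble(value = 1:4,
#'                                 rel_MAP = c(110, 90, 95, 120)))
#' class(sw) <- "wk_sweep"
#' effective_intervals(sw, "MAP")
#' @export
effective_intervals <- function(sweep, variable = c("MAP", "SAP", "DAP")) {
  stopifnot(inherits(sweep, "wk_sweep"))
  variable <- match.arg(variable)
  v <- sweep$tbl$value
  rel <- sweep$tbl[[paste0("rel_", variable)]]
  if (anyNA(rel)) {
    stop("sweep is incomplete for ", variable, ": NA relative magnitudes",
         call. = FALSE)
  }
  below <- rel < 100
  if (!any(below)) {
    return(tibble::tibble(variable = character(0), lower = numeric(0),
                          upper = numeric(0)))
  }
  r <- rle(below)
  stops <- cumsum(r$lengths)
  starts <- stops - r$lengths + 1
  lower <- upper <- numeric(0)
  for (k in which(r$values)) {
    a <- starts[k]; b <- stops[k]
    lo <- if (a == 1) v[1] else
      v[a - 1] + (v[a] - v[a - 1]) * (100 - rel[a - 1]) / (rel[a] - rel[a - 1])
    hi <- if (b == length(v)) v[length(v)] else
      v[b] + (v[b + 1] - v[b]) * (100 - rel[b]) / (rel[b + 1] - rel[b])
    lower <- c(lower, lo); upper <- c(upper, hi)
  }
  tibble::tibble(variable = variable, lower = lower, upper = upper)
}

#' Plot relative fluctuation magnitudes of a sweep
#'
#' Relative SAP/DAP/MAP curves against the swept parameter, with the 100%
#' effectiveness threshold and the effective intervals of one highlighted
#' variable shaded.
#'
#' @param object A `wk_sweep` object.
#' @param shade Variable whose effective intervals are shaded (default
#'   `"MAP"` for delay sweeps, `"DAP"` for amplitude sweeps).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.wk_sweep <- function(object,
                              shade = if (object$parameter == "tau") "MAP"
                                      else "DAP",
                              ...) {
  long <- tidyr::pivot_longer(object$tbl, -"value",
                              names_to = "variable", names_prefix = "rel_",
                              values_to = "rel")
  iv <- effective_intervals(object, shade)
  gg <- ggplot2::ggplot(long, ggplot2::aes(.data$value, .data$rel,
                                           linetype = .data$variable))
  if (nrow(iv) > 0) {
    gg <- gg + ggplot2::geom_rect(
      data = iv,
      ggplot2::aes(xmin = .data$lower, xmax = .data$upper,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, alpha = 0.15)
  }
  gg +
    ggplot2::geom_hline(yintercept = 100, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = if (object$parameter == "tau") "control delay tau (s)"
          else "control amplitude r0 (cycles/s)",
      y = "relative fluctuation magnitude (%)",
      linetype = NULL)
}
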