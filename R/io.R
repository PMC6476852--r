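#' Write the standard output files of a simulation
#'
#' Writes three files: `<prefix>_timeseries.csv` (columns `t`, `p_a`,
#' `p_c`, `p_v`, `p_I`, `phi`, `Phi`), `<prefix>_beats.csv` (columns `i`,
#' `t_i`, `RR`, `SAP`, `DAP`, `MAP`, `dV`) and `<prefix>_summary.json`
#' (parameter echo, beat count, means, standard deviations, clamp and
#' negative-ejection counters).  CSV output is RFC-4180 with a header row
#' and `.` decimal separator; numbers are written with 9 significant
#' digits so regenerated fixtures are byte-stable.
#'
#' @param sim A [wk_simulate()] result.
#' @param prefix Output path prefix.
#' @return Invisibly, the vector of file paths written.
#' @export
write_simulation <- function(sim, prefix) {
  stopifnot(inherits(sim, "wk_sim"))
  ts <- dplyr::select(sim$timeseries, "t", "p_a", "p_c", "p_v", "p_I",
                      "phi", "Phi")
  beats <- extract_beats(sim)
  paths <- paste0(prefix, c("_timeseries.csv", "_beats.csv",
                            "_summary.json"))
  write_csv9(ts, paths[1])
  write_csv9(beats, paths[2])
  g <- glance(sim)
  summary <- list(
    params = unclass(sim$params),
    settings = list(duration = sim$duration, dt = sim$dt,
                    transient = sim$transient),
    n_beats = g$n_beats, n_breaths = g$n_breaths,
    mean_hr_bpm = g$mean_hr_bpm,
    means = list(SAP = g$mean_SAP, DAP = g$mean_DAP, MAP = g$mean_MAP),
    stds = list(SAP = g$sd_SAP, DAP = g$sd_DAP, MAP = g$sd_MAP,
                RR = g$sd_RR),
    clamp_events = g$clamp_events,
    negative_ejections = g$negative_ejections
  )
  jsonlite::write_json(summary, paths[3], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}

#' Write the standard output files of a sweep
#'
#' Writes `<prefix>_sweep.csv` (columns `value`, `rel_SAP`, `rel_DAP`,
#' `rel_MAP`) and `<prefix>_intervals.json` (per-variable
#' effective-interval lists, the reference standard deviations and the
#' full parameter echo).
#'
#' @param sweep A [sweep_parameter()] result.
#' @param prefix Output path prefix.
#' @return Invisibly, the vector of file paths written.
#' @export
write_sweep <- function(sweep, prefix) {
  stopifnot(inherits(sweep, "wk_sweep"))
  paths <- paste0(prefix, c("_sweep.csv", "_intervals.json"))
  write_csv9(sweep$tbl, paths[1])
  ivs <- lapply(c(SAP = "SAP", DAP = "DAP", MAP = "MAP"), function(v) {
    iv <- effective_intervals(sweep, v)
    lapply(seq_len(nrow(iv)),
           function(k) list(lower = iv$lower[k], upper = iv$upper[k]))
  })
  out <- list(parameter = sweep$parameter,
              effective_intervals = ivs,
              reference_stds = as.list(sweep$reference_stds),
              params = unclass(sweep$params),
              settings = list(duration = sweep$duration, dt = sweep$dt,
                              transient = sweep$transient))
  jsonlite::write_json(out, paths[2], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}

# RFC-4180 CSV with 9 significant digits, for byte-stable fixtures.
write_csv9 <- function(df, path) {
  fmt <- as.data.frame(lapply(df, function(col) {
    if (is.double(col)) signif(col, 9) else col
  }))
  utils::write.csv(fmt, path, row.names = FALSE, quote = FALSE, eol = "\r\n")
  invisible(path)
}

#' Generate small canned runs as regression fixtures
#'
#' Produces, deterministically and purely from the model itself: (a) the
#' beat table of a 10-s controlled run, (b) the beat table of a 10-s
#' control-off reference run, and (c) a 5-point mini delay-sweep CSV whose
#' middle columns can be checked against freshly computed values.
#'
#' @param out_dir Writable output directory (created if missing).
#' @param r0 Control amplitude of the controlled fixture run, cycles/s.
#' @return Invisibly, the vector of file paths written.
#' @export
generate_fixtures <- function(out_dir, r0 = -0.2) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- wk_params(r0 = r0)
  sim <- wk_simulate(p, duration = 10, transient = 2)
  ref <- wk_simulate(wk_modify(p, r0 = 0), duration = 10, transient = 2)
  f1 <- file.path(out_dir, "nominal_beats.csv")
  f2 <- file.path(out_dir, "reference_beats.csv")
  write_csv9(extract_beats(sim), f1)
  write_csv9(extract_beats(ref), f2)
  sw <- sweep_parameter(p, "tau", grid = seq(0.5, 2.5, by = 0.5),
                        duration = 20, transient = 5)
  f3 <- file.path(out_dir, "mini_tau_sweep.csv")
  write_csv9(sw$tbl, f3)
  invisible(c(f1, f2, f3))
}
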