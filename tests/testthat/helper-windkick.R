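# Shared helpers for the windkick test suite.

# A hand-built wk_sim carrying an analytic arterial trace between two beats,
# for checking the beat-metric reductions against closed forms.  `p_fun`
# gives p_a(t); beats at `beat_times`; the trace carries the exact pre/post
# event rows the extractor expects.
synthetic_sim <- function(p_fun, beat_times, dt = 1e-3, transient = 0) {
  tg <- seq(beat_times[1], beat_times[length(beat_times)], by = dt)
  rows <- tibble::tibble(t = tg, p_a = p_fun(tg), event = "none")
  for (bt in beat_times) {
    rows <- dplyr::bind_rows(
      rows,
      tibble::tibble(t = bt, p_a = p_fun(bt), event = "beat_pre"),
      tibble::tibble(t = bt, p_a = p_fun(bt), event = "beat_post"))
  }
  rows <- rows[order(rows$t, match(rows$event, c("beat_pre", "beat_post",
                                                 "none"))), ]
  structure(
    list(timeseries = dplyr::mutate(rows, p_c = 0, p_v = 0, p_I = 0,
                                    phi = 0, Phi = 0),
         beats = tibble::tibble(i = seq_along(beat_times), t_i = beat_times,
                                dV = 0),
         breath_onsets = numeric(0), clamp_events = 0L,
         negative_ejections = 0L, params = wk_params(), duration = max(tg),
         dt = dt, transient = transient),
    class = "wk_sim")
}

# Direct high-precision evaluation of the phase-effectiveness form,
# independent of the compiled path.
phase_eff_oracle <- function(phi) {
  phi^1.3 * (phi - 0.45) + (1 - phi)^3 / ((1 - 0.8)^3 + (1 - phi)^3)
}
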