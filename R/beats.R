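#' Per-beat arterial-pressure records
#'
#' Reduces a simulated trajectory to the per-beat clinical variables: for
#' each inter-beat window `[t_i, t_{i+1})` entirely past the transient, the
#' systolic pressure (SAP, maximum of `p_a` on the window), diastolic
#' pressure (DAP, minimum), mean pressure (MAP, trapezoidal time-average of
#' the full waveform between consecutive systoles) and the RR interval.
#' In this model systole is the ejection instant itself, so the window
#' opens at the post-kick sample and closes just before the next beat's
#' pre-kick sample; the final incomplete interval is dropped.
#'
#' @param sim A [wk_simulate()] result.
#' @param transient Discard window, s; beats starting before it are
#'   excluded (default: the value stored in `sim`).
#' @return A tibble with one row per complete inter-beat interval:
#'   `i` (beat index), `t_i` (beat time, s), `RR` (s), `SAP`, `DAP`, `MAP`
#'   (mmHg), `dV` (ejected volume, ml).
#' @examples
#' sim <- wk_simulate(wk_params(), duration = 8, transient = 2)
#' extract_beats(sim)
#' @export
extract_beats <- function(sim, transient = sim$transient) {
  stopifnot(inherits(sim, "wk_sim"))
  bt <- sim$beats$t_i
  keep <- which(bt >= transient)
  if (length(keep) < 2) {
    stop("fewer than 2 beats after the transient window", call. = FALSE)
  }
  ts <- sim$timeseries
  # Post-kick rows open each window; everything up to (not including) the
  # next pre-kick row belongs to it.  Event rows are exact duplicates of the
  # beat times, so windows never straddle a sample segment.
  t_all <- ts$t
  ev <- ts$event
  first <- keep[1]
  last <- keep[length(keep)]
  starts <- bt[first:(last - 1)]
  ends <- bt[(first + 1):last]

  # Row ranges: for window j, rows from the post-kick row at starts[j] to the
  # pre-kick row at ends[j] inclusive.
  post_rows <- which(ev == "beat_post")
  pre_rows <- which(ev == "beat_pre")
  post_at <- post_rows[match(round(starts, 12), round(t_all[post_rows], 12))]
  pre_at <- pre_rows[match(round(ends, 12), round(t_all[pre_rows], 12))]

  n <- length(starts)
  SAP <- DAP <- MAP <- numeric(n)
  for (j in seq_len(n)) {
    rows <- post_at[j]:pre_at[j]
    tt <- t_all[rows]
    pp <- ts$p_a[rows]
    SAP[j] <- max(pp)
    DAP[j] <- min(pp)
    w <- diff(tt)
    MAP[j] <- sum(w * (pp[-1] + pp[-length(pp)]) / 2) / (tt[length(tt)] - tt[1])
  }
  tibble::tibble(
    i = first:(last - 1),
    t_i = starts,
    RR = ends - starts,
    SAP = SAP, DAP = DAP, MAP = MAP,
    dV = sim$beats$dV[first:(last - 1)]
  )
}

#' Standard deviation of a per-beat series
#'
#' Population standard deviation (divisor `N`) of one per-beat variable —
#' the square root of the total fluctuation power.  The population
#' convention is fixed for determinism; the buffering analysis only ever
#' uses ratios of like-for-like standard deviations, in which the divisor
#' cancels.
#'
#' @param records A beat table from [extract_beats()].
#' @param variable One of `"SAP"`, `"DAP"`, `"MAP"`, `"RR"`.
#' @return Standard deviation in the variable's units.
#' @examples
#' beat_series_std(tibble::tibble(SAP = c(90, 110)), "SAP")  # 10
#' @export
beat_series_std <- function(records, variable = c("SAP", "DAP", "MAP", "RR")) {
  variable <- match.arg(variable)
  x <- records[[variable]]
  if (length(x) < 2) {
    stop("need at least 2 beat records to form a standard deviation",
         call. = FALSE)
  }
  sqrt(mean((x - mean(x))^2))
}
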