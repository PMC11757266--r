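#' Hypotension / hypertension thresholds from baseline MAP
#'
#' Thresholds are defined relative to the pre-induction baseline MAP:
#' 30% below for hypotension and 30% above for hypertension.
#'
#' @param baseline_map baseline (pre-induction) MAP in mmHg, positive.
#' @return Named numeric vector `c(hypo, hyper)` in mmHg.
#' @export
map_thresholds <- function(baseline_map) {
  if (!is.finite(baseline_map) || baseline_map <= 0) {
    stop("baseline MAP must be positive", call. = FALSE)
  }
  c(hypo = 0.7 * baseline_map, hyper = 1.3 * baseline_map)
}

#' Time-weighted hypotension and hypertension
#'
#' The time-weighted (TW) metrics integrate the depth of the MAP excursion
#' beyond its threshold over the time spent beyond it: trapezoidal
#' integration of the clamped excess `max(0, threshold - MAP)` (hypotension)
#' or `max(0, MAP - threshold)` (hypertension) over the sampling grid, in
#' mmHg·min. For a constant-depth excursion this equals depth x duration;
#' for varying depth it equals mean depth x time beyond threshold.
#' Crossings between grid points are not sub-resolved beyond the trapezoid
#' rule — the data resolution is the 5-minute grid.
#'
#' @param series a complete [circulation_series].
#' @param baseline_map baseline MAP used for the thresholds; defaults to
#'   the series' first reading.
#' @return Time-weighted area in mmHg·min (non-negative).
#' @export
tw_hypotension <- function(series, baseline_map = attr(series, "baseline_map")) {
  thr <- map_thresholds(baseline_map)[["hypo"]]
  trapz_area(series$t, pmax(0, thr - series$map))
}

#' @rdname tw_hypotension
#' @export
tw_hypertension <- function(series, baseline_map = attr(series, "baseline_map")) {
  thr <- map_thresholds(baseline_map)[["hyper"]]
  trapz_area(series$t, pmax(0, series$map - thr))
}

trapz_area <- function(t, y) {
  n <- length(t)
  if (n < 2L) return(0)
  sum(diff(t) * (y[-1L] + y[-n]) / 2)
}

#' Average real variability of MAP (generalized, time-weighted)
#'
#' `arv_map` is the interval-weighted mean absolute successive MAP
#' difference, `(1/T) * sum(dt_k * |MAP[k+1] - MAP[k]|)`; `arvs_map` is its
#' squared generalization, `(1/T) * sum(|MAP[k+1] - MAP[k]|^2 / dt_k)`,
#' with `T` the total time between the first and last reading. On a uniform
#' grid `arv_map` reduces to the mean absolute successive difference.
#' Both are zero iff MAP is constant, and `arv_map` is invariant to time
#' reversal of the series.
#'
#' @param series a complete [circulation_series] with at least 2 points.
#' @return A non-negative scalar (mmHg for `arv_map`, mmHg^2/min for
#'   `arvs_map`).
#' @export
arv_map <- function(series) {
  d <- series_diffs(series)
  sum(d$dt * abs(d$dmap)) / d$Ttot
}

#' @rdname arv_map
#' @export
arvs_map <- function(series) {
  d <- series_diffs(series)
  sum(d$dmap^2 / d$dt) / d$Ttot
}

series_diffs <- function(series) {
  n <- nrow(series)
  if (n < 2L) stop("undefined metric: need at least 2 MAP readings", call. = FALSE)
  Ttot <- series$t[n] - series$t[1L]
  if (Ttot <= 0) stop("undefined metric: zero total time", call. = FALSE)
  list(dt = diff(series$t), dmap = diff(series$map), Ttot = Ttot)
}

#' All manual circulation assessment features for one patient
#'
#' @param series a complete [circulation_series].
#' @return Named numeric vector with the reserved feature names
#'   `tw_hypotension`, `tw_hypertension`, `arv_map`, `arvs_map`; thresholds
#'   are attached as the `thresholds` attribute.
#' @export
manual_metrics <- function(series) {
  thr <- map_thresholds(attr(series, "baseline_map"))
  structure(c(tw_hypotension = tw_hypotension(series),
              tw_hypertension = tw_hypertension(series),
              arv_map = arv_map(series),
              arvs_map = arvs_map(series)),
            thresholds = thr)
}
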