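#' Construct a circulation series
#'
#' A `circulation_series` holds one patient's intraoperative vital-sign
#' record on a regular sampling grid (default 5 minutes): systolic and
#' diastolic blood pressure, heart rate and pulse, plus the derived mean
#' arterial pressure (MAP) channel. The first reading is taken before
#' anesthesia induction, so `baseline_map` is the MAP at time zero.
#'
#' Missing observations are represented as `NA` and handled by
#' [impute_gaps()]. The MAP channel is recomputed from SBP/DBP whenever the
#' object is built.
#'
#' @param t time in minutes since the first reading (strictly increasing).
#' @param sbp,dbp systolic / diastolic blood pressure, mmHg.
#' @param hr,pulse heart rate and pulse, beats per minute.
#' @param patient_id identifier carried through the pipeline.
#' @param grid_minutes grid spacing in minutes (default 5).
#' @return An object of class `circulation_series`: a data frame with
#'   columns `t, sbp, dbp, hr, pulse, map` and attributes `patient_id`,
#'   `grid_minutes`, `baseline_map`.
#' @export
circulation_series <- function(t, sbp, dbp, hr, pulse,
                               patient_id = "patient", grid_minutes = 5) {
  n <- length(t)
  if (n < 2L) stop("unusable series: fewer than 2 readings", call. = FALSE)
  lens <- c(length(sbp), length(dbp), length(hr), length(pulse))
  if (any(lens != n)) stop("all channels must have the same length", call. = FALSE)
  if (any(diff(t) <= 0)) stop("timestamps must be strictly increasing", call. = FALSE)
  ok <- !is.na(sbp) & !is.na(dbp)
  if (any(sbp[ok] <= dbp[ok])) {
    stop("invalid reading: sbp must exceed dbp at every observed point", call. = FALSE)
  }
  x <- data.frame(t = as.numeric(t), sbp = as.numeric(sbp),
                  dbp = as.numeric(dbp), hr = as.numeric(hr),
                  pulse = as.numeric(pulse))
  x$map <- ifelse(ok, compute_map(ifelse(ok, sbp, dbp + 1), dbp), NA_real_)
  structure(x,
            class = c("circulation_series", "data.frame"),
            patient_id = patient_id,
            grid_minutes = grid_minutes,
            baseline_map = x$map[1L])
}

#' @export
print.circulation_series <- function(x, ...) {
  cat(sprintf("<circulation_series> patient %s: %d points, %g-min grid, %.0f min\n",
              attr(x, "patient_id"), nrow(x), attr(x, "grid_minutes"),
              x$t[nrow(x)] - x$t[1L]))
  cat(sprintf("  baseline MAP %.1f mmHg; %d missing point(s)\n",
              attr(x, "baseline_map"), sum(is.na(x$map))))
  invisible(x)
}

#' Mean arterial pressure from systolic and diastolic pressure
#'
#' Standard clinical estimate `MAP = DBP + (SBP - DBP) / 3`, applied
#' pointwise. Strictly monotone in both arguments and bounded between DBP
#' and SBP.
#'
#' @param sbp,dbp systolic / diastolic pressure in mmHg; `sbp > dbp > 0`.
#' @return MAP in mmHg.
#' @export
compute_map <- function(sbp, dbp) {
  if (any(!is.na(sbp) & !is.na(dbp) & sbp <= dbp)) {
    stop("invalid reading: sbp must exceed dbp", call. = FALSE)
  }
  if (any(!is.na(dbp) & dbp <= 0)) stop("invalid reading: dbp must be positive", call. = FALSE)
  dbp + (sbp - dbp) / 3
}

#' Resample an irregular record onto the regular grid
#'
#' Linearly interpolates each channel onto the `grid_minutes` grid spanning
#' the first to last reading. No extrapolation is performed beyond the
#' recorded range. Grid-aligned input passes through unchanged
#' (idempotence).
#'
#' @param raw a data frame with columns `t, sbp, dbp, hr, pulse` (times in
#'   minutes, possibly irregular), or a `circulation_series`.
#' @inheritParams circulation_series
#' @return A [circulation_series] on the regular grid, re-anchored at t = 0.
#' @export
regularize_grid <- function(raw, patient_id = attr(raw, "patient_id") %||% "patient",
                            grid_minutes = 5) {
  if (nrow(raw) < 2L) stop("unusable series: fewer than 2 readings", call. = FALSE)
  o <- order(raw$t)
  t0 <- raw$t[o] - raw$t[o][1L]
  grid <- seq(0, t0[length(t0)], by = grid_minutes)
  interp <- function(v) {
    obs <- !is.na(v)
    if (sum(obs) < 2L) stop("unusable series: fewer than 2 readings in a channel", call. = FALSE)
    stats::approx(t0[obs], v[o][obs], xout = grid, rule = 1)$y
  }
  circulation_series(grid, interp(raw$sbp), interp(raw$dbp),
                     interp(raw$hr), interp(raw$pulse),
                     patient_id = patient_id, grid_minutes = grid_minutes)
}

#' Fill short gaps and enforce the exclusion rule
#'
#' Isolated missing grid points are replaced by the mean of the two
#' neighbouring values; runs of two missing points are filled by linear
#' interpolation between the flanking values (which reduces to the
#' neighbour mean for single points). Leading and trailing missing points
#' are dropped and the grid re-anchored at zero. Any interior run of more
#' than two consecutive missing points — a gap longer than 10 minutes on
#' the 5-minute grid — makes the record unusable and raises an exclusion
#' error, mirroring the cohort exclusion criterion.
#'
#' Observed values are never modified.
#'
#' @param series a [circulation_series], possibly with `NA` points.
#' @return A complete [circulation_series].
#' @export
impute_gaps <- function(series) {
  gm <- attr(series, "grid_minutes")
  pid <- attr(series, "patient_id")
  channels <- c("sbp", "dbp", "hr", "pulse")
  # drop leading/trailing rows where everything is missing
  miss_all <- Reduce(`&`, lapply(series[channels], is.na))
  keep <- which(!miss_all)
  if (length(keep) < 2L) stop("unusable series: fewer than 2 observed points", call. = FALSE)
  series <- series[keep[1L]:keep[length(keep)], , drop = FALSE]
  out <- list()
  for (ch in channels) {
    v <- series[[ch]]
    na <- is.na(v)
    if (any(na)) {
      r <- rle(na)
      run_len <- r$lengths[r$values]
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      # leading/trailing NA in a single channel only: also excluded territory —
      # treat as interior (cannot interpolate), handled by rule = 1 below
      if (any(run_len > 2L)) {
        stop(sprintf("excluded: patient %s channel %s has a gap > 10 min (%d consecutive missing points)",
                     pid, ch, max(run_len)), call. = FALSE)
      }
      if (na[1L] || na[length(na)]) {
        stop(sprintf("excluded: patient %s channel %s missing at the series boundary with other channels observed",
                     pid, ch), call. = FALSE)
      }
      v <- stats::approx(series$t[!na], v[!na], xout = series$t, rule = 1)$y
    }
    out[[ch]] <- v
  }
  circulation_series(series$t - series$t[1L], out$sbp, out$dbp, out$hr, out$pulse,
                     patient_id = pid, grid_minutes = gm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
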