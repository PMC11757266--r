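#' Feature row for a growing series prefix
#'
#' Recomputes the manual metrics and the quantified time-series features on
#' the prefix of a circulation series up to `t_cut` minutes, as the
#' real-time scorer does at every grid step. The baseline MAP is always
#' the first reading, so thresholds never change as the prefix grows.
#' Features undefined on a short prefix carry `NA` (imputed as 0 after
#' normalization at scoring time); a paired `<name>__undefined` indicator
#' block records which entries were undefined.
#'
#' @param series a complete (imputed) [circulation_series].
#' @param t_cut prefix end, minutes; must be at or after the first grid
#'   point.
#' @return Named numeric vector: manual + quantified features followed by
#'   their `__undefined` indicators.
#' @export
prefix_features <- function(series, t_cut) {
  if (t_cut < series$t[1L]) {
    stop("t_cut precedes the first grid point", call. = FALSE)
  }
  keep <- series$t <= t_cut
  n <- sum(keep)
  if (n >= 2L) {
    pre <- circulation_series(series$t[keep], series$sbp[keep], series$dbp[keep],
                              series$hr[keep], series$pulse[keep],
                              patient_id = attr(series, "patient_id"),
                              grid_minutes = attr(series, "grid_minutes"))
    # baseline is reading 0 of the full record = reading 0 of any prefix
    vals <- c(manual_metrics(pre), extract_series_features(pre))
  } else {
    template <- c(manual_metrics(series), extract_series_features(series))
    vals <- sentinel(names(template))
  }
  ind <- stats::setNames(as.numeric(is.na(vals)),
                         paste0(names(vals), "__undefined"))
  c(vals, ind)
}

#' Real-time prediction-score trajectory for one patient
#'
#' Replays a surgery: at every grid time the manual and quantified features
#' are recomputed on the data observed so far, joined with the static
#' clinical covariates, normalized with the model's training-cohort
#' parameters (no per-prefix refit), and scored by the fitted classifier.
#' Prefixes shorter than `min_points` grid points return the training
#' PLOS prevalence as a fallback score and are flagged in `fallback`.
#' The final non-fallback score equals the static full-series prediction
#' exactly.
#'
#' @param model a fitted [plos_model()].
#' @param series the patient's [circulation_series] (imputed internally if
#'   it contains missing points).
#' @param clinical one-row data frame (or named vector) with the clinical
#'   covariates used at training time.
#' @param min_points minimum prefix length before real scoring (default 5
#'   points, i.e. 25 minutes on the 5-minute grid).
#' @return An object of class `score_trajectory`: data frame with columns
#'   `t_min`, `score`, `fallback`.
#' @export
score_trajectory <- function(model, series, clinical, min_points = 5L) {
  if (!inherits(model, "plos_model")) stop("model must be a plos_model", call. = FALSE)
  if (anyNA(series$map)) series <- impute_gaps(series)
  clin <- unlist(clinical[setdiff(names(clinical), c("patient_id", "los_days"))])
  need_clin <- intersect(model$norm$features, names(clin))
  times <- series$t
  scores <- numeric(length(times))
  fallback <- logical(length(times))
  for (k in seq_along(times)) {
    if (k < min_points) {
      scores[k] <- model$bundle$prevalence
      fallback[k] <- TRUE
      next
    }
    fx <- prefix_features(series, times[k])
    row <- c(fx[intersect(model$norm$features, names(fx))],
             clin[need_clin])
    miss <- setdiff(model$norm$features, names(row))
    if (length(miss)) {
      stop("schema error: trajectory input lacks feature(s): ",
           paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
    }
    x <- matrix(row[model$norm$features], nrow = 1,
                dimnames = list(NULL, model$norm$features))
    xn <- apply_minmax(x, model$norm, na_fill = 0)
    scores[k] <- predict(model$bundle, xn)
  }
  structure(data.frame(t_min = times, score = scores, fallback = fallback),
            class = c("score_trajectory", "data.frame"),
            patient_id = attr(series, "patient_id"))
}

#' @export
print.score_trajectory <- function(x, ...) {
  cat(sprintf("<score_trajectory> patient %s: %d grid points, final score %.3f\n",
              attr(x, "patient_id"), nrow(x), x$score[nrow(x)]))
  invisible(x)
}

#' Plot a prediction-score trajectory
#'
#' @param x a `score_trajectory`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.score_trajectory <- function(x, ...) {
  plot(x$t_min, x$score, type = "s", ylim = c(0, 1),
       xlab = "time since first reading (min)", ylab = "PLOS prediction score",
       main = sprintf("Real-time prediction score (%s)", attr(x, "patient_id")),
       ...)
  graphics::points(x$t_min[x$fallback], x$score[x$fallback], pch = 1, col = "grey50")
  invisible(x)
}
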