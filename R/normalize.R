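#' Fit min-max normalization parameters on a training feature matrix
#'
#' Records the per-feature minimum and maximum observed on the training
#' rows only. Apply with [apply_minmax()]; validation values outside the
#' training range are deliberately not clipped and may fall outside
#' \[0, 1\].
#'
#' @param train numeric matrix (patients x features) with column names.
#' @return An object of class `minmax_params`.
#' @export
fit_minmax <- function(train) {
  if (is.null(colnames(train))) stop("feature matrix must have column names", call. = FALSE)
  mins <- apply(train, 2L, function(v) suppressWarnings(min(v, na.rm = TRUE)))
  maxs <- apply(train, 2L, function(v) suppressWarnings(max(v, na.rm = TRUE)))
  mins[!is.finite(mins)] <- 0   # all-NA column: map everything to the sentinel
  maxs[!is.finite(maxs)] <- 0
  structure(list(min = mins, max = maxs, features = colnames(train)),
            class = "minmax_params")
}

#' Apply fitted min-max normalization
#'
#' Maps `x` to `(x - min) / (max - min)` per feature. A feature constant on
#' the training data (max = min) maps to 0 everywhere. Columns are matched
#' by name; unknown columns raise a schema error.
#'
#' @param x numeric matrix with column names drawn from the fitted features.
#' @param params a `minmax_params` object from [fit_minmax()].
#' @param na_fill optional value substituted for missing entries *after*
#'   normalization (used for undefined features on short series prefixes);
#'   default `NULL` leaves `NA` in place.
#' @return Normalized matrix with the same shape and column names.
#' @export
apply_minmax <- function(x, params, na_fill = NULL) {
  if (!inherits(params, "minmax_params")) stop("params must come from fit_minmax()", call. = FALSE)
  unknown <- setdiff(colnames(x), params$features)
  if (length(unknown)) {
    stop("schema error: unknown feature(s): ", paste(utils::head(unknown, 5), collapse = ", "),
         call. = FALSE)
  }
  mn <- params$min[colnames(x)]
  mx <- params$max[colnames(x)]
  rng <- mx - mn
  out <- sweep(x, 2L, mn, `-`)
  out <- sweep(out, 2L, ifelse(rng > 0, rng, 1), `/`)
  out[, rng == 0] <- 0
  if (!is.null(na_fill)) out[is.na(out)] <- na_fill
  out
}

#' @export
print.minmax_params <- function(x, ...) {
  cat(sprintf("<minmax_params> %d features (training-cohort ranges)\n", length(x$features)))
  invisible(x)
}

#' Persist / restore min-max parameters as JSON keyed by feature name
#'
#' @param params a `minmax_params` object.
#' @param path JSON file path.
#' @return `write_minmax` returns `path` invisibly; `read_minmax` returns
#'   the restored `minmax_params`.
#' @export
write_minmax <- function(params, path) {
  jsonlite::write_json(
    list(min = as.list(params$min), max = as.list(params$max)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_minmax
#' @export
read_minmax <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(min = unlist(j$min), max = unlist(j$max),
                 features = names(j$min)),
            class = "minmax_params")
}
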