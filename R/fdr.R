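#' Dual-test FDR feature selection
#'
#' Screens every feature column against the binary outcome with a
#' type-dependent univariate test — a two-sided Mann-Whitney rank-sum test
#' for real-valued features, Fisher's exact test for binary features — and
#' controls the false discovery rate with the Benjamini-Yekutieli step-up
#' procedure at level `q` (default 0.01). Benjamini-Yekutieli is used
#' rather than Benjamini-Hochberg because feature columns derived from the
#' same underlying series are strongly dependent. Constant features are
#' assigned p = 1 and are never selected.
#'
#' @param features numeric matrix (patients x features) with column names.
#' @param labels binary outcome vector (0/1), both classes present.
#' @param q FDR level.
#' @return An object of class `fdr_selection`: a data frame with one row
#'   per feature (`feature`, `p`, `test`, `p_adj`, `rejected`, `rank`),
#'   ordered as the input columns; `q` is attached as an attribute.
#' @export
fdr_select <- function(features, labels, q = 0.01) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    stop("labels must contain both classes", call. = FALSE)
  }
  if (nrow(features) != length(labels)) {
    stop("features and labels disagree in length", call. = FALSE)
  }
  res <- vapply(seq_len(ncol(features)), function(j) {
    x <- features[, j]
    ok <- !is.na(x)
    u <- unique(x[ok])
    if (length(u) <= 1L) return(c(p = 1, binary = NA_real_))
    if (length(u) == 2L) {
      p <- stats::fisher.test(table(factor(x[ok], levels = sort(u)),
                                    factor(labels[ok], levels = 0:1)))$p.value
      return(c(p = p, binary = 1))
    }
    p <- suppressWarnings(
      stats::wilcox.test(x[ok & labels == 1L], x[ok & labels == 0L],
                         exact = FALSE)$p.value)
    c(p = if (is.na(p)) 1 else p, binary = 0)
  }, numeric(2))
  p <- res["p", ]
  test <- ifelse(is.na(res["binary", ]), "constant",
                 ifelse(res["binary", ] == 1, "exact", "rank-sum"))
  p_adj <- stats::p.adjust(p, method = "BY")
  out <- data.frame(feature = colnames(features),
                    p = p, test = test, p_adj = p_adj,
                    rejected = p_adj <= q,
                    rank = rank(p, ties.method = "first"),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, class = c("fdr_selection", "data.frame"), q = q)
}

#' @export
print.fdr_selection <- function(x, ...) {
  cat(sprintf("<fdr_selection> %d features screened at q = %g: %d selected\n",
              nrow(x), attr(x, "q"), sum(x$rejected)))
  top <- x[order(x$rank), , drop = FALSE]
  print.data.frame(utils::head(top[top$rejected, c("feature", "test", "p", "p_adj")], 10),
                   row.names = FALSE, digits = 3)
  invisible(x)
}

#' Selected feature names
#'
#' @param selection an `fdr_selection`.
#' @return Character vector of selected feature names in screening order.
#' @export
selected_features <- function(selection) {
  selection$feature[selection$rejected]
}
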