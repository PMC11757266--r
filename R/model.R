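#' Assign prolonged-length-of-stay labels
#'
#' The PLOS label is 1 iff the length of stay strictly exceeds the cohort
#' median; a stay equal to the median is not prolonged. The median is
#' computed over the full cohort before any train/validation split.
#'
#' @param los_days numeric vector of lengths of stay (days).
#' @return Integer 0/1 vector with the cohort median attached as the
#'   `median_los` attribute.
#' @export
assign_plos_labels <- function(los_days) {
  if (length(los_days) == 0L) stop("empty cohort", call. = FALSE)
  med <- stats::median(los_days)
  structure(as.integer(los_days > med), median_los = med)
}

#' Random 8:2 cohort split
#'
#' Uniform random partition without stratification: the primary cohort gets
#' `ceiling(ratio * n)` patients, the validation cohort the remainder
#' (so 804 patients split 644/160 at the default 8:2 ratio).
#' Deterministic under `seed`.
#'
#' @param n cohort size (>= 10).
#' @param ratio primary fraction.
#' @param seed integer seed.
#' @return List with integer index vectors `primary` and `validation`.
#' @export
split_cohort <- function(n, ratio = 0.8, seed = 1L) {
  if (n < 10L) stop("need at least 10 patients to split", call. = FALSE)
  set.seed(seed)
  prim <- sort(sample.int(n, ceiling(ratio * n)))
  list(primary = prim, validation = setdiff(seq_len(n), prim))
}

#' Build the full feature matrix for a cohort
#'
#' Imputes each patient's series ([impute_gaps()]), then computes the
#' manual circulation metrics, the quantified time-series features for all
#' five channels, and appends the clinical covariates. Patients whose
#' series fail the gap-exclusion rule are dropped with a logged reason.
#'
#' @param cohort a `plos_cohort` (or a list with `series` and `covariates`).
#' @return Numeric matrix (patients x features) with a `provenance`
#'   attribute (`"manual"`, `"quantified"` or `"clinical"` per column) and
#'   an `excluded` attribute naming dropped patients.
#' @export
build_features <- function(cohort) {
  ids <- cohort$covariates$patient_id
  excluded <- character(0)
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    s <- cohort$series[[ids[i]]]
    row <- tryCatch({
      cs <- impute_gaps(s)
      c(manual_metrics(cs), extract_series_features(cs))
    }, error = function(e) {
      excluded <<- c(excluded, paste0(ids[i], ": ", conditionMessage(e)))
      NULL
    })
    rows[[i]] <- row
  }
  keep <- !vapply(rows, is.null, logical(1))
  mat <- do.call(rbind, rows[keep])
  rownames(mat) <- ids[keep]
  clin_cols <- setdiff(names(cohort$covariates), c("patient_id", "los_days"))
  clin <- as.matrix(cohort$covariates[keep, clin_cols, drop = FALSE])
  rownames(clin) <- ids[keep]
  out <- cbind(mat, clin)
  prov <- c(rep("manual", 4L),
            rep("quantified", ncol(mat) - 4L),
            rep("clinical", ncol(clin)))
  names(prov) <- colnames(out)
  structure(out, provenance = prov, excluded = excluded)
}

#' Train a tree-ensemble PLOS classifier
#'
#' Fits a binary probability classifier with xgboost: either a gradient
#' boosted tree model (`"gbt"`: 300 rounds, depth 3, learning rate 0.1) or
#' a random forest grown as a single round of 500 parallel trees with row
#' and column subsampling (`"rf"`). Both share one deterministic predict
#' path and exact tree-SHAP attributions.
#'
#' @param x numeric feature matrix (normalized), no missing values.
#' @param y binary labels.
#' @param algorithm `"gbt"` or `"rf"`.
#' @param seed integer seed.
#' @param hyper named list overriding the defaults (`nrounds`, `max_depth`,
#'   `eta`, `num_parallel_tree`, `subsample`, `colsample_bynode`).
#' @return An object of class `plos_bundle`.
#' @export
train_model <- function(x, y, algorithm = c("gbt", "rf"), seed = 1L,
                        hyper = list()) {
  algorithm <- match.arg(algorithm)
  y <- as.integer(y)
  if (nrow(x) != length(y)) stop("feature/label length mismatch", call. = FALSE)
  defaults <- if (algorithm == "gbt") {
    list(nrounds = 300L, max_depth = 3L, eta = 0.1,
         num_parallel_tree = 1L, subsample = 1, colsample_bynode = 1)
  } else {
    list(nrounds = 1L, max_depth = 8L, eta = 1,
         num_parallel_tree = 500L, subsample = 0.632,
         colsample_bynode = max(1, floor(sqrt(ncol(x)))) / ncol(x))
  }
  h <- utils::modifyList(defaults, hyper)
  params <- list(objective = "binary:logistic",
                 max_depth = h$max_depth, eta = h$eta,
                 num_parallel_tree = h$num_parallel_tree,
                 subsample = h$subsample, colsample_bynode = h$colsample_bynode,
                 nthread = 1L, seed = seed)
  dtrain <- xgboost::xgb.DMatrix(x, label = y)
  booster <- xgboost::xgb.train(params = params, data = dtrain,
                                nrounds = h$nrounds, verbose = 0)
  structure(list(booster = booster, algorithm = algorithm,
                 manifest = colnames(x), prevalence = mean(y),
                 seed = seed, hyper = h,
                 base_margin = stats::qlogis(xgb_base_score(booster))),
            class = "plos_bundle")
}

#' @export
print.plos_bundle <- function(x, ...) {
  cat(sprintf("<plos_bundle> %s, %d features, training prevalence %.2f, seed %d\n",
              x$algorithm, length(x$manifest), x$prevalence, x$seed))
  invisible(x)
}

#' Score a feature matrix with a trained bundle
#'
#' @param object a `plos_bundle`.
#' @param newdata numeric matrix carrying (at least) the manifest columns.
#' @param ... unused.
#' @return Predicted PLOS probabilities in \[0, 1\].
#' @export
predict.plos_bundle <- function(object, newdata, ...) {
  miss <- setdiff(object$manifest, colnames(newdata))
  if (length(miss)) {
    stop("schema error: missing manifest feature(s): ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  }
  m <- newdata[, object$manifest, drop = FALSE]
  stats::predict(object$booster, xgboost::xgb.DMatrix(m))
}

#' Exact tree-SHAP feature attributions
#'
#' Per-patient SHAP values in margin (log-odds) space with the
#' path-dependent (cover-weighted) value function; features are ranked by
#' mean absolute SHAP value. The per-patient values plus the base value
#' reproduce the model margin (local accuracy).
#'
#' For the shallow boosted-tree bundles the attributions are computed
#' in-package in double precision, exactly, by enumerating feature subsets
#' within each tree; for the deep random-forest bundles (whose trees touch
#' far too many features for enumeration) the values come from xgboost's
#' native `predcontrib`, which evaluates the same quantity in single
#' precision.
#'
#' @param bundle a `plos_bundle`.
#' @param x feature matrix to attribute over.
#' @return List with `values` (patients x features matrix), `base`
#'   (expected margin per patient), and `ranking` (data frame `feature`,
#'   `mean_abs_shap`, sorted decreasing).
#' @export
shap_importance <- function(bundle, x) {
  if (!inherits(bundle, "plos_bundle")) {
    stop("unsupported model: need a tree-ensemble plos_bundle", call. = FALSE)
  }
  m <- x[, bundle$manifest, drop = FALSE]
  if (bundle$algorithm == "gbt") {
    sh <- exact_tree_shap(bundle, m)
    base <- sh$base
    vals <- sh$values
  } else {
    contrib <- stats::predict(bundle$booster, xgboost::xgb.DMatrix(m),
                              predcontrib = TRUE)
    bias_col <- ncol(contrib)  # xgboost appends the expected margin last
    base <- contrib[, bias_col]
    vals <- contrib[, -bias_col, drop = FALSE]
    colnames(vals) <- bundle$manifest
  }
  imp <- colMeans(abs(vals))
  list(values = vals, base = base,
       ranking = data.frame(feature = names(sort(imp, decreasing = TRUE)),
                            mean_abs_shap = as.numeric(sort(imp, decreasing = TRUE)),
                            row.names = NULL))
}

xgb_base_score <- function(booster) {
  cfg <- xgboost::xgb.config(booster)
  if (is.character(cfg)) cfg <- jsonlite::fromJSON(cfg)
  as.numeric(cfg$learner$learner_model_param$base_score)
}

#' Evaluate predicted scores against held-out labels
#'
#' AUROC by the Mann-Whitney (rank) construction with DeLong 95%
#' confidence interval, plus overall accuracy and the confusion matrix at
#' the 0.5 probability threshold.
#'
#' @param labels binary labels, both classes present.
#' @param scores predicted probabilities.
#' @return An object of class `eval_report`: list with `auroc`,
#'   `auroc_ci95`, `oa`, `confusion` (2x2 table), `n`.
#' @export
eval_report <- function(labels, scores) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    stop("validation labels contain a single class", call. = FALSE)
  }
  roc <- pROC::roc(response = labels, predictor = scores,
                   levels = c(0, 1), direction = "<", quiet = TRUE)
  ci <- as.numeric(pROC::ci.auc(roc, method = "delong"))
  pred <- as.integer(scores >= 0.5)
  confusion <- table(factor(pred, levels = 0:1), factor(labels, levels = 0:1),
                     dnn = c("predicted", "observed"))
  structure(list(auroc = as.numeric(pROC::auc(roc)),
                 auroc_ci95 = c(lo = ci[1], hi = ci[3]),
                 oa = mean(pred == labels),
                 confusion = confusion,
                 n = length(labels)),
            class = "eval_report")
}

#' @rdname eval_report
#' @param bundle a `plos_bundle`.
#' @param x validation feature matrix.
#' @param y validation labels.
#' @export
evaluate_bundle <- function(bundle, x, y) {
  eval_report(y, predict(bundle, x))
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("AUROC %.3f (95%% CI %.3f-%.3f), OA %.1f%%, n = %d\n",
              x$auroc, x$auroc_ci95[1], x$auroc_ci95[2], 100 * x$oa, x$n))
  print(x$confusion)
  invisible(x)
}
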