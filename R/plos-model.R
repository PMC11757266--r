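#' Fit a PLOS prediction model on a cohort
#'
#' End-to-end fit of the PLOS (prolonged length of stay) classifier on an
#' intraoperative cohort: label assignment against the cohort-wide median
#' LOS, a random 8:2 primary/validation split, dual-test FDR screening of
#' the quantified circulation features on the primary cohort, min-max
#' normalization fitted on the primary cohort, tree-ensemble training, and
#' held-out evaluation with SHAP attributions.
#'
#' Two feature sets mirror the two ways of assessing intraoperative
#' circulation: `"quantified"` uses the machine-learned time-series
#' features (FDR-selected at level `q`), `"manual"` uses the four manual
#' metrics (time-weighted hypotension/hypertension, ARV, ARVs). Both are
#' combined with the same clinical covariates. FDR screening applies to
#' the quantified features only; the four manual metrics and the clinical
#' covariates always enter their models.
#'
#' @param cohort a `plos_cohort` (from [simulate_cohort()] or assembled
#'   from files).
#' @param feature_set `"quantified"` or `"manual"`.
#' @param algorithm `"gbt"` (gradient boosted trees) or `"rf"` (random
#'   forest).
#' @param split_ratio primary-cohort fraction (default 0.8).
#' @param q FDR level for quantified-feature screening (default 0.01).
#' @param seed integer seed controlling the split and the ensemble.
#' @param hyper hyperparameter overrides, see [train_model()].
#' @param features optional precomputed [build_features()] matrix (reused
#'   across fits on the same cohort).
#' @return An object of class `plos_model` with components `bundle`,
#'   `selection` (the `fdr_selection`, quantified set only), `norm`
#'   (min-max parameters), `eval` (validation `eval_report`), `shap`
#'   (primary-cohort ranking), `median_los`, `split`, `labels`,
#'   `feature_set`, `algorithm`, `seed`.
#' @export
plos_model <- function(cohort,
                       feature_set = c("quantified", "manual"),
                       algorithm = c("gbt", "rf"),
                       split_ratio = 0.8, q = 0.01, seed = 1L,
                       hyper = list(), features = NULL) {
  feature_set <- match.arg(feature_set)
  algorithm <- match.arg(algorithm)
  if (is.null(features)) features <- build_features(cohort)
  prov <- attr(features, "provenance")
  ids <- rownames(features)
  cov <- cohort$covariates[match(ids, cohort$covariates$patient_id), ]
  labels <- assign_plos_labels(cov$los_days)
  split <- split_cohort(length(ids), ratio = split_ratio, seed = seed)

  clin <- names(prov)[prov == "clinical"]
  selection <- NULL
  if (feature_set == "quantified") {
    quant <- names(prov)[prov == "quantified"]
    selection <- fdr_select(features[split$primary, quant, drop = FALSE],
                            labels[split$primary], q = q)
    chosen <- selected_features(selection)
    if (!length(chosen)) {
      warning("FDR selected no quantified features; using all of them", call. = FALSE)
      chosen <- quant
    }
  } else {
    chosen <- names(prov)[prov == "manual"]
  }
  cols <- c(chosen, clin)

  norm <- fit_minmax(features[split$primary, cols, drop = FALSE])
  xall <- apply_minmax(features[, cols, drop = FALSE], norm, na_fill = 0)
  bundle <- train_model(xall[split$primary, , drop = FALSE],
                        labels[split$primary], algorithm = algorithm,
                        seed = seed, hyper = hyper)
  eval <- evaluate_bundle(bundle, xall[split$validation, , drop = FALSE],
                          labels[split$validation])
  shap <- shap_importance(bundle, xall[split$primary, , drop = FALSE])

  structure(list(bundle = bundle, selection = selection, norm = norm,
                 eval = eval, shap = shap$ranking,
                 median_los = attr(labels, "median_los"),
                 split = split, labels = labels, ids = ids,
                 feature_set = feature_set, algorithm = algorithm,
                 seed = seed,
                 validation_scores = predict(bundle, xall[split$validation, , drop = FALSE])),
            class = "plos_model")
}

#' @export
print.plos_model <- function(x, ...) {
  cat(sprintf("PLOS prediction model (%s features + clinical, %s)\n",
              x$feature_set, x$bundle$algorithm))
  cat(sprintf("  cohort n = %d (primary %d / validation %d), median LOS %g days\n",
              length(x$ids), length(x$split$primary), length(x$split$validation),
              x$median_los))
  if (!is.null(x$selection)) {
    cat(sprintf("  FDR (q = %g): %d of %d quantified features selected\n",
                attr(x$selection, "q"), sum(x$selection$rejected), nrow(x$selection)))
  }
  cat(sprintf("  validation AUROC %.3f (95%% CI %.3f-%.3f), OA %.1f%%\n",
              x$eval$auroc, x$eval$auroc_ci95[1], x$eval$auroc_ci95[2],
              100 * x$eval$oa))
  invisible(x)
}

#' @export
summary.plos_model <- function(object, n_top = 10L, ...) {
  print(object)
  cat("\nConfusion matrix (validation, threshold 0.5):\n")
  print(object$eval$confusion)
  cat(sprintf("\nTop %d features by mean |SHAP| (primary cohort):\n", n_top))
  print(utils::head(object$shap, n_top), row.names = FALSE, digits = 3)
  invisible(object)
}

#' Score new patients with a fitted PLOS model
#'
#' @param object a `plos_model`.
#' @param newdata a `plos_cohort`, or a raw feature matrix from
#'   [build_features()] on one.
#' @param ... unused.
#' @return Named vector of PLOS probabilities.
#' @export
predict.plos_model <- function(object, newdata, ...) {
  feats <- if (inherits(newdata, "plos_cohort")) build_features(newdata) else newdata
  x <- apply_minmax(feats[, object$norm$features, drop = FALSE], object$norm,
                    na_fill = 0)
  stats::setNames(predict(object$bundle, x), rownames(feats))
}

#' @export
residuals.plos_model <- function(object, ...) {
  y <- object$labels[object$split$validation]
  stats::setNames(y - object$validation_scores,
                  object$ids[object$split$validation])
}

#' Plot a fitted PLOS model
#'
#' Draws the validation ROC curve and a bar chart of the top features by
#' mean absolute SHAP value.
#'
#' @param x a `plos_model`.
#' @param n_top number of features in the SHAP panel.
#' @param ... unused.
#' @export
plot.plos_model <- function(x, n_top = 15L, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4.5, 9, 2.5, 1))
  on.exit(graphics::par(op))
  y <- x$labels[x$split$validation]
  roc <- pROC::roc(response = y, predictor = x$validation_scores,
                   levels = c(0, 1), direction = "<", quiet = TRUE)
  graphics::par(mar = c(4.5, 4.5, 2.5, 1))
  plot(roc, main = sprintf("Validation ROC (AUROC %.3f)", x$eval$auroc),
       legacy.axes = TRUE)
  top <- utils::head(x$shap, n_top)
  graphics::par(mar = c(4.5, 9, 2.5, 1))
  graphics::barplot(rev(top$mean_abs_shap), names.arg = rev(top$feature),
                    horiz = TRUE, las = 1, cex.names = 0.6,
                    xlab = "mean |SHAP| (log-odds)",
                    main = "Feature importance")
  invisible(x)
}

#' Compare manual vs quantified circulation assessment models
#'
#' Runs the four-model grid — {quantified, manual} features x {random
#' forest, gradient boosted trees} — on the same cohort, split and clinical
#' covariates, and tabulates validation AUROC (with DeLong 95% CI) and
#' overall accuracy for each.
#'
#' @param cohort a `plos_cohort`.
#' @param seed split/training seed.
#' @param q FDR level for the quantified feature set.
#' @param hyper hyperparameter overrides applied to every model.
#' @param features optional precomputed [build_features()] matrix.
#' @return Data frame with one row per model (`feature_set`, `algorithm`,
#'   `auroc`, `ci_lo`, `ci_hi`, `oa`); fitted models attached as the
#'   `models` attribute.
#' @export
compare_assessments <- function(cohort, seed = 1L, q = 0.01, hyper = list(),
                                features = NULL) {
  if (is.null(features)) features <- build_features(cohort)
  grid <- expand.grid(feature_set = c("quantified", "manual"),
                      algorithm = c("gbt", "rf"),
                      stringsAsFactors = FALSE)
  models <- vector("list", nrow(grid))
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    m <- plos_model(cohort, feature_set = grid$feature_set[i],
                    algorithm = grid$algorithm[i], q = q, seed = seed,
                    hyper = hyper, features = features)
    models[[i]] <- m
    rows[[i]] <- data.frame(feature_set = grid$feature_set[i],
                            algorithm = grid$algorithm[i],
                            auroc = m$eval$auroc,
                            ci_lo = m$eval$auroc_ci95[[1]],
                            ci_hi = m$eval$auroc_ci95[[2]],
                            oa = m$eval$oa)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, models = models)
}
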