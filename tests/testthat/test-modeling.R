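test_that("PLOS labels use the strict above-median rule", {
  l1 <- assign_plos_labels(c(8, 10, 10, 12))
  expect_equal(as.integer(l1), c(0L, 0L, 0L, 1L))
  expect_equal(attr(l1, "median_los"), 10)
  expect_equal(as.integer(assign_plos_labels(rep(9, 6))), rep(0L, 6))
  l3 <- assign_plos_labels(c(8, 12))
  expect_equal(as.integer(l3), c(0L, 1L))
  expect_equal(attr(l3, "median_los"), 10)
  expect_error(assign_plos_labels(numeric(0)), "empty")
})

test_that("the 8:2 split has the documented sizes and is seeded", {
  sp <- split_cohort(804, seed = 4)
  expect_length(sp$primary, 644)
  expect_length(sp$validation, 160)
  expect_setequal(c(sp$primary, sp$validation), 1:804)
  sp10 <- split_cohort(10, seed = 4)
  expect_length(sp10$primary, 8)
  expect_length(sp10$validation, 2)
  expect_identical(split_cohort(804, seed = 4), sp)
  expect_false(identical(split_cohort(804, seed = 5), sp))
  expect_error(split_cohort(9), "at least 10")
})

test_that("a separable problem is learned almost perfectly by both ensembles", {
  set.seed(51)
  n <- 500
  x <- matrix(runif(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- as.integer(x[, 3] > 0.5)
  for (algo in c("gbt", "rf")) {
    b <- train_model(x, y, algo, seed = 1)
    expect_gte(eval_report(y, predict(b, x))$auroc, 0.99)
  }
})

test_that("null features give validation AUROC centred at 0.5", {
  aucs <- vapply(1:50, function(s) {
    set.seed(s)
    n <- 120
    x <- matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, paste0("f", 1:10)))
    y <- rbinom(n, 1, 0.5)
    tr <- 1:90; va <- 91:120
    if (length(unique(y[va])) < 2) return(NA_real_)
    b <- train_model(x[tr, ], y[tr], "gbt", seed = s, hyper = list(nrounds = 40))
    eval_report(y[va], predict(b, x[va, ]))$auroc
  }, numeric(1))
  expect_lt(abs(mean(aucs, na.rm = TRUE) - 0.5), 0.05)
})

test_that("training is deterministic under a fixed seed", {
  set.seed(52)
  x <- matrix(rnorm(600), 100, 6, dimnames = list(NULL, paste0("f", 1:6)))
  y <- rbinom(100, 1, 0.5)
  p1 <- predict(train_model(x, y, "rf", seed = 3), x)
  p2 <- predict(train_model(x, y, "rf", seed = 3), x)
  expect_identical(p1, p2)
})

test_that("AUROC equals the concordant-pair fraction and handles degenerate scores", {
  set.seed(53)
  for (i in 1:50) {
    n <- sample(10:30, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # ties likely
    expect_equal(eval_report(y, s)$auroc, oracle_auc(y, s), tolerance = 1e-12)
  }
  y <- rep(0:1, 10)
  expect_equal(eval_report(y, as.numeric(y))$auroc, 1)
  expect_equal(eval_report(y, as.numeric(y))$oa, 1)
  expect_equal(eval_report(y, rep(0.3, 20))$auroc, 0.5)
  expect_error(eval_report(rep(1, 5), runif(5)), "single class")
})

test_that("DeLong intervals contain the estimate and tighten with n", {
  make_scores <- function(n, seed) {
    set.seed(seed)
    y <- rbinom(n, 1, 0.5)
    list(y = y, s = plogis(rnorm(n, mean = y)))
  }
  small <- make_scores(100, 61)
  big <- make_scores(1000, 62)
  es <- eval_report(small$y, small$s)
  eb <- eval_report(big$y, big$s)
  expect_true(es$auroc_ci95[1] <= es$auroc && es$auroc <= es$auroc_ci95[2])
  expect_true(eb$auroc_ci95[1] <= eb$auroc && eb$auroc <= eb$auroc_ci95[2])
  expect_lt(diff(eb$auroc_ci95), diff(es$auroc_ci95))
  expect_equal(sum(es$confusion), 100)
})

test_that("SHAP attributions are locally accurate and concentrate on the only signal", {
  set.seed(63)
  n <- 300
  x <- matrix(runif(n * 4), n, 4, dimnames = list(NULL, paste0("f", 1:4)))
  x[, 2:4] <- 0.5   # constant: the model can only use f1
  y <- as.integer(x[, 1] + rnorm(n, 0, 0.1) > 0.5)
  b <- train_model(x, y, "gbt", seed = 2)
  sh <- shap_importance(b, x)
  margin <- intracirc:::predict_margin_exact(b, x)
  expect_lt(max(abs(rowSums(sh$values) + sh$base - margin)), 1e-6)
  # the double-precision margin agrees with the library predict path
  marg32 <- predict(b$booster, xgboost::xgb.DMatrix(x), outputmargin = TRUE)
  expect_lt(max(abs(margin - marg32)), 1e-3)
  tot <- sum(sh$ranking$mean_abs_shap)
  expect_equal(sh$ranking$mean_abs_shap[sh$ranking$feature == "f1"] / tot, 1)
})

test_that("in-package tree SHAP agrees with the library's single-precision path", {
  set.seed(64)
  n <- 200
  x <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("f", 1:6)))
  y <- rbinom(n, 1, plogis(x[, 1] - x[, 4]))
  b <- train_model(x, y, "gbt", seed = 4, hyper = list(nrounds = 80))
  sh <- shap_importance(b, x)
  contrib <- predict(b$booster, xgboost::xgb.DMatrix(x), predcontrib = TRUE)
  expect_lt(max(abs(contrib[, 1:6] - sh$values)), 1e-3)
  expect_lt(max(abs(contrib[, 7] - sh$base)), 1e-3)
})

test_that("fitted pipeline ignores validation rows when selecting and normalizing", {
  co <- quick_cohort(n = 120, seed = 21, len = 40)
  f <- build_features(co)
  m <- plos_model(co, "quantified", "gbt", seed = 6, features = f)
  f2 <- f
  f2[m$split$validation, attr(f, "provenance") == "quantified"] <-
    f2[m$split$validation, attr(f, "provenance") == "quantified"] * 3 + 1
  attr(f2, "provenance") <- attr(f, "provenance")
  m2 <- plos_model(co, "quantified", "gbt", seed = 6, features = f2)
  expect_identical(m$selection$rejected, m2$selection$rejected)
  expect_identical(m$norm, m2$norm)
  # and the trained booster scores the primary cohort identically
  expect_identical(predict(m$bundle, matrix(0.4, 1, length(m$bundle$manifest),
                                            dimnames = list(NULL, m$bundle$manifest))),
                   predict(m2$bundle, matrix(0.4, 1, length(m2$bundle$manifest),
                                             dimnames = list(NULL, m2$bundle$manifest))))
})

test_that("the four-model comparison is reproducible and complete", {
  co <- quick_cohort(n = 100, seed = 22, len = 40)
  tab <- compare_assessments(co, seed = 2)
  expect_equal(nrow(tab), 4)
  expect_setequal(tab$feature_set, c("quantified", "manual"))
  expect_setequal(tab$algorithm, c("gbt", "rf"))
  expect_true(all(tab$auroc >= 0 & tab$auroc <= 1))
  expect_true(all(tab$ci_lo <= tab$auroc & tab$auroc <= tab$ci_hi))
  tab2 <- compare_assessments(co, seed = 2)
  expect_equal(tab, tab2, ignore_attr = TRUE)
})

test_that("permuting patient order permutes predictions only", {
  co <- quick_cohort(n = 60, seed = 23, len = 30)
  f <- build_features(co)
  set.seed(1); perm <- sample(nrow(f))
  co2 <- list(series = co$series, covariates = co$covariates[perm, ],
              truth = co$truth, config = co$config)
  class(co2) <- "plos_cohort"
  f2 <- build_features(co2)
  expect_equal(f2[rownames(f), ], f[, ], ignore_attr = TRUE)
})
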