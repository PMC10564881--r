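test_that("trapezoidal AUC equals brute-force concordance, ties included", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc(c(0.1, 0.2, 0.9, 0.8), c(1, 1, 0, 0))$auc, 0)
  # 6-point set with a tie
  s <- c(0.9, 0.5, 0.5, 0.4, 0.3, 0.1)
  l <- c(1, 1, 0, 1, 0, 0)
  expect_equal(roc_auc(s, l)$auc, concordance_auc(s, l))
  # random toy sets up to 50 points, with heavy ties
  set.seed(1)
  for (i in 1:25) {
    n <- sample(4:50, 1)
    sc <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    lb <- c(0, 1, rbinom(n - 2, 1, 0.5))
    expect_equal(roc_auc(sc, lb)$auc, concordance_auc(sc, lb))
  }
  expect_error(roc_auc(runif(5), rep(1, 5)), "both classes")
  # independent cross-check against pROC
  set.seed(10)
  sc <- runif(80)
  lb <- rbinom(80, 1, 0.5)
  expect_equal(roc_auc(sc, lb)$auc,
               as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE))))
})

test_that("ROC curves run from (0,0) to (1,1) monotonically", {
  set.seed(2)
  curve <- roc_auc(runif(60), rbinom(60, 1, 0.4))$curve
  expect_equal(unlist(curve[1, c("fpr", "tpr")]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(curve[nrow(curve), c("fpr", "tpr")]),
               c(fpr = 1, tpr = 1))
  expect_true(all(diff(curve$fpr) >= 0))
  expect_true(all(diff(curve$tpr) >= 0))
})

test_that("held-out testing refits frozen models and scores the untouched test set", {
  set.seed(3)
  x <- matrix(rnorm(300 * 6), 300, 6,
              dimnames = list(NULL, sprintf("f%03d", 1:6)))
  y <- as.integer(x[, 2] - x[, 5] > 0)  # perfectly separable by 2 features
  tr <- 1:200; te <- 201:300
  models <- list(fake_record(bic = 1, subset = c(2, 5),
                             hyperparams = list(mixing = 0.1,
                                                strength = 0.001)))
  rep <- test_holdout(models, x[tr, ], y[tr], x[te, ], y[te],
                      spec = estimator_spec("logistic_elasticnet"), seed = 1)
  expect_equal(rep$accuracy, 1)
  expect_equal(rep$precision, 1)
  expect_equal(rep$recall, 1)
  expect_equal(rep$auc, 1)
  # a feature missing from the test table is a hard error
  expect_error(
    test_holdout(models, x[tr, ], y[tr], x[te, 1:3], y[te],
                 spec = estimator_spec("logistic_elasticnet")),
    "missing from the test table"
  )
})

test_that("permutation importance isolates the features a model uses", {
  set.seed(4)
  x <- matrix(rnorm(250 * 3), 250, 3,
              dimnames = list(NULL, c("used", "unused1", "unused2")))
  y <- rbinom(250, 1, plogis(2 * x[, 1]))
  f <- function(m) plogis(2 * m[, 1])  # model that ignores columns 2-3
  imp <- permutation_importance(f, x, y, n_repeats = 10, seed = 1)
  expect_gt(imp$importance[1], 0.2)
  expect_lt(max(abs(imp$importance[2:3])), 0.05)
  # sole informative feature: importance near baseline AUC - 0.5
  base <- roc_auc(f(x), y)$auc
  expect_equal(imp$importance[1], base - 0.5, tolerance = 0.1)
  # permuting the order of OTHER columns leaves importances unchanged
  imp2 <- permutation_importance(function(m) plogis(2 * m[, "used"]),
                                 x[, c(3, 1, 2)], y, n_repeats = 10, seed = 1)
  expect_equal(imp2$importance[imp2$feature == "used"],
               imp$importance[imp$feature == "used"], tolerance = 1e-12)
})

test_that("sampled Shapley values satisfy the linear closed form and local accuracy", {
  set.seed(5)
  xb <- matrix(rnorm(25 * 3), 25, 3, dimnames = list(NULL, c("a", "b", "c")))
  beta <- c(2, -1, 0.5)
  f <- function(m) as.numeric(m %*% beta)
  sh <- shapley_importance(f, xb, xb[1:3, ], n_samples = 200, seed = 1)
  expected <- sweep(xb[1:3, ], 2, colMeans(xb)) %*% diag(beta)
  expect_lt(max(abs(sh$attributions - expected)), 1e-6)
  expect_lt(max(abs(rowSums(sh$attributions) -
                      (f(xb[1:3, ]) - sh$base_value))), 1e-9)
})

test_that("sampled Shapley matches exhaustive coalition enumeration for a tree model", {
  set.seed(6)
  x <- matrix(rnorm(120 * 3), 120, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- as.integer(x[, 1] + 0.5 * x[, 2] > 0)
  spec <- estimator_spec("boosted_trees")
  est <- fit_estimator(
    make_estimator(spec, list(eta = 0.3, max_depth = 2, n_estimators = 50,
                              subsample = 1, colsample = 1, lambda = 1,
                              gamma = 0)), x, y, seed = 1)
  f <- function(m) predict_proba(est, m)
  xb <- x[1:12, ]
  sh <- shapley_importance(f, xb, x[13:15, ], n_samples = 200, seed = 2)
  for (r in 1:3) {
    oracle <- exhaustive_shapley(f, xb, x[12 + r, ])
    expect_lt(max(abs(sh$attributions[r, ] - oracle)), 1e-2)
  }
})

test_that("duplicate features receive symmetric Shapley credit", {
  set.seed(7)
  xb <- matrix(rnorm(30), 15, 2, dimnames = list(NULL, c("a", "b")))
  xb[, 2] <- xb[, 1]
  f <- function(m) m[, 1] + m[, 2]
  sh <- shapley_importance(f, xb, xb[1:4, ], n_samples = 100, seed = 3)
  expect_equal(sh$attributions[, 1], sh$attributions[, 2], tolerance = 1e-8)
})

test_that("elastic-net odds ratios come from an unpenalized refit of the selected set", {
  set.seed(8)
  x <- matrix(rnorm(200 * 3), 200, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rbinom(200, 1, plogis(0.8 * x[, 1]))
  spec <- estimator_spec("logistic_elasticnet")
  est <- fit_estimator(make_estimator(spec, list(mixing = 1, strength = 0.05)),
                       x, y)
  ors <- lr_odds_ratios(est, x, y)
  # independent oracle: direct likelihood maximization over the selected set
  sel <- ors$predictor
  nll <- function(par) {
    eta <- par[1] + x[, sel, drop = FALSE] %*% par[-1]
    -sum(y * eta - log1p(exp(eta)))
  }
  opt <- optim(rep(0, length(sel) + 1), nll, method = "BFGS")
  expect_equal(ors$odds_ratio, exp(opt$par[-1]), tolerance = 1e-3,
               ignore_attr = TRUE)
  # heavy penalty empties the selected set: intercept-only report
  est0 <- fit_estimator(make_estimator(spec, list(mixing = 1, strength = 50)),
                        x, y)
  ors0 <- lr_odds_ratios(est0, x, y)
  expect_equal(ors0$predictor, "(Intercept)")
})

test_that("report regeneration from the same artifacts is byte-identical", {
  set.seed(9)
  x <- matrix(rnorm(200 * 4), 200, 4,
              dimnames = list(NULL, sprintf("f%03d", 1:4)))
  y <- rbinom(200, 1, plogis(x[, 1]))
  models <- list(fake_record(1, c(1, 2),
                             hyperparams = list(mixing = 0.5, strength = 0.05)))
  rep <- test_holdout(models, x[1:150, ], y[1:150], x[151:200, ], y[151:200],
                      spec = estimator_spec("logistic_elasticnet"))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  iel_report(rep, dir = d1)
  iel_report(rep, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
  pl <- plot_roc(rep)
  expect_s3_class(pl, "ggplot")
})
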