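make_ft <- function(values, mask = NULL) feature_table(values, mask)

test_that("sparse features are dropped strictly above the threshold", {
  set.seed(1)
  vals <- matrix(rnorm(1000), 100, 10)
  mask <- matrix(TRUE, 100, 10)
  rates <- seq(0, 0.9, by = 0.1)
  for (j in 1:10) mask[seq_len(round(100 * rates[j])), j] <- FALSE
  ft <- make_ft(vals, mask)
  out <- drop_sparse_features(ft, 0.40)
  expect_equal(ncol(out$values), 5)  # rates 0.0 .. 0.4 retained
  expect_true(all(colMeans(!out$mask) <= 0.40))
  # a feature at 41% missing goes, at exactly 40% stays
  m2 <- matrix(TRUE, 100, 2)
  m2[1:41, 1] <- FALSE; m2[1:40, 2] <- FALSE
  out2 <- drop_sparse_features(make_ft(matrix(rnorm(200), 100, 2), m2), 0.40)
  expect_equal(ncol(out2$values), 1)
  expect_equal(attr(out2, "dropped"), "f001")
  # fully observed table unchanged
  full <- make_ft(vals)
  expect_equal(drop_sparse_features(full)$values, full$values)
  # all dropped -> error
  expect_error(drop_sparse_features(make_ft(vals, matrix(FALSE, 100, 10))),
               "all features")
})

test_that("outlier trimming clips to mean +/- 3 sd of the same partition", {
  # a single large outlier inflates the sd; with few points it can sit
  # inside mean + 3 sd ({0,0,0,0,100} has bound 154.2) - verify no clipping
  x5 <- c(0, 0, 0, 0, 100)
  out5 <- trim_outliers(make_ft(matrix(x5, 5, 1)))
  expect_equal(unname(out5$values[5, 1]), 100)
  # with a broad baseline the outlier is genuinely clipped to mean + 3 sd
  x <- c(rep(0, 99), 100)
  out <- trim_outliers(make_ft(matrix(x, 100, 1)))
  ub <- mean(x) + 3 * sd(x)
  expect_equal(unname(out$values[100, 1]), ub)
  expect_equal(unname(out$values[1:99, 1]), rep(0, 99))
  # values within bounds: identity
  set.seed(2)
  ft2 <- make_ft(matrix(runif(50), 50, 1))
  expect_equal(trim_outliers(ft2)$values, ft2$values)
  # constant column: identity with warning
  ft3 <- make_ft(matrix(2, 10, 1))
  expect_warning(out3 <- trim_outliers(ft3), "constant")
  expect_equal(out3$values, ft3$values)
})

test_that("masked NNMF imputes only missing cells and beats column means", {
  # identity when complete
  ftc <- make_ft(matrix(runif(60), 20, 3))
  expect_identical(impute_nnmf(ftc, rank = 2)$values, ftc$values)
  # rank-2 structure, 20% MCAR
  set.seed(21)
  w <- matrix(runif(200 * 2), 200, 2)
  h <- matrix(runif(2 * 30), 2, 30)
  truth <- w %*% h
  mask <- matrix(runif(200 * 30) > 0.2, 200, 30)
  ft <- make_ft(ifelse(mask, truth, NA))
  imp <- suppressWarnings(impute_nnmf(ft, rank = 2, seed = 2))
  # observed entries bit-identical
  expect_identical(imp$values[mask], truth[mask])
  rmse <- sqrt(mean((imp$values[!mask] - truth[!mask])^2))
  cm <- truth
  for (j in 1:30) cm[!mask[, j], j] <- mean(truth[mask[, j], j])
  rmse_cm <- sqrt(mean((cm[!mask] - truth[!mask])^2))
  expect_lt(rmse, rmse_cm)
  # objective over observed cells is non-increasing
  obj <- attr(imp, "nnmf")$objective
  expect_true(all(diff(obj) <= 1e-8 * pmax(obj[-length(obj)], 1)))
})

test_that("feature agglomeration pools merged columns as the leaf mean", {
  x <- rnorm(25); y <- rnorm(25)
  # one column: unchanged
  expect_equal(as.numeric(agglomerate_items(cbind(a = x))), x)
  # duplicates: score equals either column
  expect_equal(as.numeric(agglomerate_items(cbind(a = x, b = x))), x)
  # {x, x, y}: brute-force mean of the merge-tree leaves
  expect_equal(as.numeric(agglomerate_items(cbind(a = x, b = x, c = y))),
               (x + x + y) / 3)
})

test_that("min-max scaling is fit on train and applied unchanged to test", {
  ft <- make_ft(matrix(c(2, 4, 6, 1, 1, 1), 3, 2))
  sc <- scale_minmax(ft)
  expect_equal(sc$values[, 1], c(0, 0.5, 1), ignore_attr = TRUE)
  expect_equal(sc$values[, 2], rep(0, 3), ignore_attr = TRUE)  # constant -> 0
  # test value above the train max stays above 1, no clipping
  te <- make_ft(matrix(c(8, 3, 2, 2), 2, 2))
  out <- apply_minmax(te, attr(sc, "minmax"))
  expect_equal(out$values[1, 1], 1.5, ignore_attr = TRUE)
})

test_that("normalizing-transform selection keeps normal data and fixes lognormal data", {
  set.seed(31)
  xn <- rnorm(300)
  sel_n <- select_normalizing_transform(xn)
  expect_equal(sel_n$report$transform, "none")
  xl <- exp(rnorm(300))
  sel_l <- select_normalizing_transform(xl)
  expect_true(sel_l$report$transform %in% c("power", "quantile"))
  expect_lt(sel_l$report$stat_after, sel_l$report$stat_before)
  # fitted transform applies to new data without refitting
  out_new <- apply_transform(xl[1:10], sel_l$transformer)
  expect_length(out_new, 10)
  expect_warning(select_normalizing_transform(rep(1, 30)), "constant")
})

test_that("target binarization labels exactly-zero agglomerated scores as not-case", {
  items <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 0, 2), c(3, 1, 1))
  colnames(items) <- c("i1", "i2", "i3")
  tg <- binarize_target(items)
  expect_equal(tg$labels, c(0L, 1L, 1L, 1L))
  expect_equal(tg$source_items, c("i1", "i2", "i3"))
  expect_warning(binarize_target(matrix(0, 4, 2)), "single-class")
})

test_that("SMOTE-ENN interpolates minority rows and moves the class ratio up", {
  set.seed(41)
  n <- 250
  x <- matrix(rnorm(n * 5), n, 5)
  y <- rbinom(n, 1, 0.12)
  x[y == 1, 1] <- x[y == 1, 1] + 2  # give the minority some structure
  rs <- resample_smoteenn(x, binary_target(y), seed = 6)
  expect_true(all(rs$target$labels %in% c(0L, 1L)))
  expect_gt(mean(rs$target$labels == 1), mean(y == 1))
  # every synthetic row lies on a segment between its two minority parents
  syn <- which(rs$info$origin == "synthetic")
  pre_enn <- rbind(x, matrix(NA, length(syn), 5))
  for (i in syn) {
    a <- x[rs$info$parent_a[i], ]
    b <- x[rs$info$parent_b[i], ]
    g <- rs$info$gap[i]
    pre_enn[i, ] <- a + g * (b - a)
  }
  kept <- rs$info$kept
  expect_equal(rs$x, pre_enn[kept, , drop = FALSE], tolerance = 1e-12)
  # every surviving original majority row is carried through unchanged
  maj_kept <- which(rs$info$origin == "original" & rs$info$label == 0 & kept)
  expect_true(all(apply(x[maj_kept, , drop = FALSE], 1, function(r) {
    any(apply(rs$x, 1, function(q) all(q == r)))
  })))
})

test_that("SMOTE reduces k with a warning for tiny minorities", {
  set.seed(42)
  x <- matrix(rnorm(40), 20, 2)
  y <- c(rep(1, 3), rep(0, 17))
  expect_warning(resample_smoteenn(x, binary_target(y), seed = 1),
                 "reducing SMOTE k")
})

test_that("univariate odds ratios match cross-product arithmetic and invert with negation", {
  # 2x2 table a=10, b=5, c=5, d=10 -> OR = 4
  x <- c(rep(1, 15), rep(0, 15))
  y <- c(rep(1, 10), rep(0, 5), rep(1, 5), rep(0, 10))
  or <- univariate_odds_ratio(x, binary_target(y))
  expect_equal(or$odds_ratio, 4, tolerance = 1e-6)
  or_neg <- univariate_odds_ratio(-x, binary_target(y))
  expect_equal(or_neg$odds_ratio, 1 / or$odds_ratio, tolerance = 1e-6)
})

test_that("odds-ratio confidence intervals cover 1 for independent features", {
  covered <- 0
  for (r in 1:100) {
    set.seed(100 + r)
    x <- rnorm(150)
    y <- rbinom(150, 1, 0.4)
    ci <- univariate_odds_ratio(x, binary_target(y))
    covered <- covered + (ci$ci_lower <= 1 && 1 <= ci$ci_upper)
  }
  expect_gte(covered, 90)
})

test_that("the fitted pipeline never learns from the test partition", {
  spec <- cohort_spec(n_subjects = 300, n_features = 20, missing_rate = 0.15,
                      latent_rank = 3, seed = 51)
  coh <- generate_cohort(spec)
  s <- split_cohort(coh$table, list(), 0.7, seed = 1)
  prep <- suppressWarnings(prep_fit(s$train$table, nnmf_rank = 3, seed = 2))
  te1 <- prep_apply(prep, s$test$table)
  # poison the test partition and refit: every fitted parameter is unchanged
  poisoned <- s$test$table
  poisoned$values[poisoned$mask] <- poisoned$values[poisoned$mask] * 10 + 5
  prep2 <- suppressWarnings(prep_fit(s$train$table, nnmf_rank = 3, seed = 2))
  expect_identical(prep$minmax, prep2$minmax)
  expect_identical(prep$dropped, prep2$dropped)
  expect_identical(prep$nnmf, prep2$nnmf)
  expect_identical(prep$transformers, prep2$transformers)
  expect_identical(prep$train$values, prep2$train$values)
  # train partition output of the scaling step is inside [0,1]
  sc <- scale_minmax(suppressWarnings(
    impute_nnmf(trim_outliers(drop_sparse_features(s$train$table)),
                rank = 3, seed = 2)))
  expect_true(all(sc$values >= 0 & sc$values <= 1))
})
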