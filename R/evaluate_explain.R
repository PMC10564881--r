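#' Test optimized models on the held-out partition
#'
#' Each retained model (frozen hyperparameters + feature subset) is refit on
#' the full (optionally resampled) training partition and scored on the
#' untouched test partition: accuracy, precision and recall at probability
#' threshold 0.5, plus the ROC curve and AUC. No resampling is ever applied
#' to the test partition.
#'
#' @param result An `iel_result`, or a list of `fitness_record`s.
#' @param train_x,train_y Training predictors/labels used for refitting
#'   (pass the resampled training set here).
#' @param test_x,test_y Held-out predictors/labels.
#' @param spec The [estimator_spec()] (defaults to the one in `result`).
#' @param seed Integer seed for stochastic refits.
#' @param threshold Probability threshold for the class metrics.
#' @return A `test_report`: tibble with one row per model (rank, accuracy,
#'   precision, recall, auc, n_features), ROC curves in `attr(, "curves")`
#'   and the per-metric best model ranks in `attr(, "best")`.
#' @export
test_holdout <- function(result, train_x, train_y, test_x, test_y,
                         spec = NULL, seed = 1L, threshold = 0.5) {
  models <- if (inherits(result, "iel_result")) result$best else result
  if (is.null(spec)) {
    stopifnot(inherits(result, "iel_result"))
    spec <- result$spec
  }
  train_x <- as.matrix(train_x); test_x <- as.matrix(test_x)
  curves <- list()
  rows <- lapply(seq_along(models), function(i) {
    chr <- models[[i]]$chromosome
    feats <- colnames(train_x)[chr$subset]
    if (!all(feats %in% colnames(test_x))) {
      stop("test_holdout: feature(s) missing from the test table: ",
           paste(setdiff(feats, colnames(test_x)), collapse = ", "))
    }
    est <- make_estimator(spec, chr$hyperparams)
    est <- fit_estimator(est, train_x[, feats, drop = FALSE], train_y,
                         seed = substream_seed(seed, paste0("refit", i)))
    pr <- predict_proba(est, test_x[, feats, drop = FALSE])
    pred <- as.integer(pr >= threshold)
    tp <- sum(pred == 1 & test_y == 1)
    fp <- sum(pred == 1 & test_y == 0)
    fn <- sum(pred == 0 & test_y == 1)
    roc <- roc_auc(pr, test_y)
    curves[[i]] <<- roc$curve
    tibble::tibble(
      rank = i,
      accuracy = mean(pred == test_y),
      precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
      recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      auc = roc$auc,
      n_features = length(feats)
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "curves") <- curves
  attr(out, "best") <- list(
    by_auc = out$rank[which.max(out$auc)],
    by_accuracy = out$rank[which.max(out$accuracy)],
    by_precision = out$rank[which.max(out$precision)],
    by_recall = out$rank[which.max(out$recall)]
  )
  class(out) <- c("test_report", class(out))
  out
}

#' Permutation feature importance
#'
#' Mean drop in a score (default AUC) when one feature's column is permuted,
#' over `n_repeats` seeded permutations; the standard deviation over repeats
#' is reported alongside.
#'
#' @param predict_fun Function taking a predictor matrix and returning
#'   scores, or a fitted `evx_estimator`.
#' @param x Predictor matrix.
#' @param y Binary labels.
#' @param n_repeats Number of permutations per feature (>= 5 recommended).
#' @param seed Integer seed.
#' @param metric Function `(scores, labels) -> scalar`; default AUC.
#' @return Tibble: `feature`, `importance` (mean score drop), `sd`.
#' @export
permutation_importance <- function(predict_fun, x, y, n_repeats = 10,
                                   seed = 1L, metric = NULL) {
  if (inherits(predict_fun, "evx_estimator")) {
    est <- predict_fun
    predict_fun <- function(newx) predict_proba(est, newx)
  }
  if (is.null(metric)) metric <- function(s, l) roc_auc(s, l)$auc
  x <- as.matrix(x)
  baseline <- metric(predict_fun(x), y)
  # one row permutation per repeat, shared across features, so a feature's
  # importance does not depend on the order of the other columns
  perms <- with_seed(substream_seed(seed, "perm"), {
    lapply(seq_len(n_repeats), function(r) sample.int(nrow(x)))
  })
  drops <- vapply(seq_len(ncol(x)), function(j) {
    vapply(seq_len(n_repeats), function(r) {
      xp <- x
      xp[, j] <- xp[perms[[r]], j]
      baseline - metric(predict_fun(xp), y)
    }, numeric(1))
  }, numeric(n_repeats))
  drops <- matrix(drops, nrow = n_repeats)
  tibble::tibble(
    feature = colnames(x),
    importance = colMeans(drops),
    sd = apply(drops, 2, stats::sd)
  )
}

#' Sampling-based Shapley attributions
#'
#' Permutation-sampling Shapley values: for each explained row, features are
#' introduced in random order on top of a background row, and each feature
#' is credited with its marginal change in model output. Contributions along
#' one permutation telescope to `f(x) - f(background)`, so the attributions
#' of each row sum exactly to the model output minus the mean background
#' output over the sampled pairs (local accuracy). When the number of
#' (permutation, background) combinations is small enough they are
#' enumerated exhaustively and the result is exact.
#'
#' @param predict_fun Function from predictor matrix to model output, or a
#'   fitted `evx_estimator`.
#' @param x_background Background matrix (reference distribution).
#' @param x_explain Rows to explain.
#' @param n_samples Sampling budget per explained row.
#' @param seed Integer seed.
#' @return A list: `attributions` (rows x features), `base_value` per row,
#'   `mean_abs` per feature.
#' @export
shapley_importance <- function(predict_fun, x_background, x_explain,
                               n_samples = 128, seed = 1L) {
  if (inherits(predict_fun, "evx_estimator")) {
    est <- predict_fun
    predict_fun <- function(newx) predict_proba(est, newx)
  }
  xb <- as.matrix(x_background)
  xe <- as.matrix(x_explain)
  stopifnot(nrow(xb) >= 1)
  p <- ncol(xe)
  n_perm_total <- factorial(p)
  exact <- is.finite(n_perm_total) && n_perm_total * nrow(xb) <= n_samples
  perms_exact <- if (exact) all_permutations(p) else NULL
  attr_mat <- matrix(0, nrow(xe), p, dimnames = list(NULL, colnames(xe)))
  base <- numeric(nrow(xe))
  with_seed(substream_seed(seed, "shapley"), {
    for (r in seq_len(nrow(xe))) {
      if (exact) {
        combos <- expand.grid(perm = seq_len(nrow(perms_exact)),
                              bg = seq_len(nrow(xb)))
        perms <- perms_exact[combos$perm, , drop = FALSE]
        bgs <- combos$bg
      } else {
        perms <- t(vapply(seq_len(n_samples), function(i) sample.int(p),
                          integer(p)))
        bgs <- sample.int(nrow(xb), n_samples, replace = TRUE)
      }
      ns <- nrow(perms)
      # build the chain of step vectors for all samples, then predict once
      chain <- matrix(0, ns * (p + 1), p)
      for (s in seq_len(ns)) {
        z <- xb[bgs[s], ]
        chain[(s - 1) * (p + 1) + 1, ] <- z
        for (step in seq_len(p)) {
          z[perms[s, step]] <- xe[r, perms[s, step]]
          chain[(s - 1) * (p + 1) + 1 + step, ] <- z
        }
      }
      colnames(chain) <- colnames(xe)
      preds <- predict_fun(chain)
      contrib <- numeric(p)
      for (s in seq_len(ns)) {
        offs <- (s - 1) * (p + 1) + 1
        diffs <- diff(preds[offs:(offs + p)])
        contrib[perms[s, ]] <- contrib[perms[s, ]] + diffs
      }
      attr_mat[r, ] <- contrib / ns
      base[r] <- mean(preds[seq(1, ns * (p + 1), by = p + 1)])
    }
  })
  list(
    attributions = attr_mat,
    base_value = base,
    mean_abs = colMeans(abs(attr_mat))
  )
}

all_permutations <- function(p) {
  if (p == 1) return(matrix(1, 1, 1))
  sub <- all_permutations(p - 1)
  do.call(rbind, lapply(seq_len(p), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Odds ratios of a fitted elastic-net logistic model
#'
#' Penalized coefficient intervals are not well-defined, so the selected
#' (nonzero-coefficient) predictors are refit without penalty and per-unit
#' odds ratios with Wald 95% confidence intervals are reported. An empty
#' selected set yields an intercept-only row.
#'
#' @param est A fitted `evx_logistic_elasticnet` estimator.
#' @param x,y The data used for the unpenalized refit.
#' @return Tibble: `predictor`, `odds_ratio`, `ci_lower`, `ci_upper`.
#' @export
lr_odds_ratios <- function(est, x, y) {
  stopifnot(inherits(est, "evx_logistic_elasticnet"))
  x <- as.matrix(x)
  b <- as.numeric(stats::coef(est$fit))[-1]
  sel <- which(abs(b) > 0)
  if (!length(sel)) {
    fit <- stats::glm(y ~ 1, family = stats::binomial())
    co <- summary(fit)$coefficients
    return(tibble::tibble(
      predictor = "(Intercept)",
      odds_ratio = exp(co[1, 1]),
      ci_lower = exp(co[1, 1] - 1.96 * co[1, 2]),
      ci_upper = exp(co[1, 1] + 1.96 * co[1, 2])
    ))
  }
  df <- as.data.frame(x[, sel, drop = FALSE])
  fit <- stats::glm(y ~ ., data = df, family = stats::binomial())
  co <- summary(fit)$coefficients[-1, , drop = FALSE]
  tibble::tibble(
    predictor = colnames(df),
    odds_ratio = exp(co[, 1]),
    ci_lower = exp(co[, 1] - 1.96 * co[, 2]),
    ci_upper = exp(co[, 1] + 1.96 * co[, 2])
  )
}

#' Assemble and write a run report
#'
#' Produces the metric grid per model, the final-predictor importance list
#' (permutation and Shapley side by side) and the ROC point series, and
#' writes them as CSV/JSON under `dir`. Regenerating the report from the
#' same artifacts is byte-identical.
#'
#' @param test_report A `test_report` from [test_holdout()].
#' @param importance Optional tibble joining permutation and Shapley values
#'   per feature.
#' @param dir Output directory (created if needed); `NULL` = don't write.
#' @return The report list (`metrics`, `importance`, `roc`), invisibly if
#'   written.
#' @export
iel_report <- function(test_report, importance = NULL, dir = NULL) {
  curves <- attr(test_report, "curves")
  best <- attr(test_report, "best")
  roc_points <- dplyr::bind_rows(lapply(seq_along(curves), function(i) {
    dplyr::mutate(curves[[i]], rank = i, .before = 1)
  }))
  rep_list <- list(
    metrics = tibble::as_tibble(test_report),
    best = best,
    importance = importance,
    roc = roc_points
  )
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(rep_list$metrics, file.path(dir, "metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(rep_list$roc, file.path(dir, "roc_points.csv"),
                     row.names = FALSE)
    if (!is.null(importance)) {
      utils::write.csv(importance, file.path(dir, "importance.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(
      list(best = best,
           metrics = rep_list$metrics),
      file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA
    )
    return(invisible(rep_list))
  }
  rep_list
}

#' ROC curves of a test report
#'
#' @param object A `test_report`.
#' @param ranks Which model ranks to draw (default: the best model by AUC).
#' @param ... Unused.
#' @export
plot_roc <- function(object, ranks = NULL, ...) {
  curves <- attr(object, "curves")
  if (is.null(ranks)) ranks <- attr(object, "best")$by_auc
  df <- dplyr::bind_rows(lapply(ranks, function(i) {
    dplyr::mutate(curves[[i]], rank = factor(i), .before = 1)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                   colour = .data$rank)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  colour = "model rank") +
    ggplot2::theme_minimal()
}
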