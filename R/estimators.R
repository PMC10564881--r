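#' Declare a hyperparameter search space
#'
#' One row per hyperparameter: its type, bounds (or choices), whether the
#' scale is logarithmic, and the mutation shift used by the evolutionary
#' operators (in the same units; log-space units for log-scaled parameters).
#'
#' @param ... One or more `space_real()`, `space_integer()` or
#'   `space_categorical()` rows.
#' @return A `search_space` tibble.
#' @export
search_space <- function(...) {
  out <- dplyr::bind_rows(...)
  stopifnot(all(c("name", "type", "lower", "upper", "log", "shift", "choices")
                %in% names(out)))
  bad <- out$type != "categorical" &
    (!is.finite(out$lower) | !is.finite(out$upper) |
       out$shift <= 0)
  if (any(bad)) stop("search_space: bounds must be finite and shifts positive")
  class(out) <- c("search_space", class(out))
  out
}

space_row <- function(name, type, lower = NA_real_, upper = NA_real_,
                      log = FALSE, shift = NA_real_, choices = list(NULL)) {
  tibble::tibble(name = name, type = type, lower = lower, upper = upper,
                 log = log, shift = shift, choices = choices)
}

#' @rdname search_space
#' @param name Hyperparameter name.
#' @param lower,upper Bounds (finite).
#' @param log Log-uniform sampling / log-space mutation.
#' @param shift Mutation shift; default 10% of the bound width (log-space
#'   width for log-scaled parameters).
#' @export
space_real <- function(name, lower, upper, log = FALSE, shift = NULL) {
  width <- if (log) log(upper) - log(lower) else upper - lower
  space_row(name, "real", lower, upper, log,
            if (is.null(shift)) 0.1 * width else shift)
}

#' @rdname search_space
#' @export
space_integer <- function(name, lower, upper, shift = NULL) {
  space_row(name, "integer", lower, upper, FALSE,
            if (is.null(shift)) max(1, round(0.1 * (upper - lower))) else shift)
}

#' @rdname search_space
#' @param choices Vector of allowed values.
#' @export
space_categorical <- function(name, choices) {
  space_row(name, "categorical", shift = 1, choices = list(choices))
}

#' Default search space for a classifier family
#'
#' Broad defaults: the elastic-net mixing parameter is naturally bounded in
#' \[0, 1\]; the remaining ranges are set generously for exploration. They
#' are this package's defaults, not canonical values.
#'
#' @param family `"logistic_elasticnet"`, `"boosted_trees"` or
#'   `"neural_net"`.
#' @return A `search_space`.
#' @export
default_search_space <- function(family) {
  switch(
    family,
    logistic_elasticnet = search_space(
      space_real("mixing", 0, 1),
      space_real("strength", 1e-3, 1e3, log = TRUE)
    ),
    boosted_trees = search_space(
      space_real("eta", 0.01, 0.5),
      space_integer("max_depth", 2, 10),
      space_integer("n_estimators", 50, 500),
      space_real("subsample", 0.5, 1),
      space_real("colsample", 0.5, 1),
      space_real("lambda", 0, 10),
      space_real("gamma", 0, 5)
    ),
    neural_net = search_space(
      space_real("learning_rate", 1e-5, 1e-1, log = TRUE),
      space_integer("batch_size", 16, 256),
      space_integer("epochs", 10, 200)
    ),
    stop("unknown family: ", family)
  )
}

#' Estimator specification: family, fixed settings and search space
#'
#' Fixed parts follow the study design: the neural net is a 3 x 300-unit
#' ReLU network with a softmax output and early stopping (patience 3 on
#' validation loss); boosted trees use the gbtree booster; the logistic
#' model is an elastic net.
#'
#' @param family Classifier family.
#' @param space A `search_space` (default [default_search_space()]).
#' @param fixed Named list overriding fixed settings (e.g. smaller hidden
#'   layers for quick experiments, or a fixed hyperparameter omitted from
#'   the search space).
#' @return An `estimator_spec`.
#' @export
estimator_spec <- function(family = c("logistic_elasticnet", "boosted_trees",
                                      "neural_net"),
                           space = NULL, fixed = list()) {
  family <- match.arg(family)
  if (is.null(space)) space <- default_search_space(family)
  defaults <- switch(
    family,
    logistic_elasticnet = list(mixing = 0.5, strength = 1),
    boosted_trees = list(eta = 0.3, max_depth = 6, n_estimators = 100,
                         subsample = 1, colsample = 1, lambda = 1, gamma = 0),
    neural_net = list(learning_rate = 1e-3, batch_size = 32, epochs = 50,
                      hidden = c(300, 300, 300), patience = 3,
                      val_fraction = 0.1)
  )
  defaults[names(fixed)] <- fixed
  structure(list(family = family, space = space, fixed = defaults),
            class = "estimator_spec")
}

check_in_space <- function(space, hyperparams) {
  for (i in seq_len(nrow(space))) {
    nm <- space$name[i]
    if (!nm %in% names(hyperparams)) {
      stop("hyperparameter '", nm, "' missing from assignment")
    }
    v <- hyperparams[[nm]]
    if (space$type[i] == "categorical") {
      if (!v %in% space$choices[[i]]) {
        stop("hyperparameter '", nm, "' outside its declared choices")
      }
    } else if (v < space$lower[i] - 1e-9 || v > space$upper[i] + 1e-9) {
      stop("hyperparameter '", nm, "' outside its declared bounds")
    }
  }
  invisible(TRUE)
}

#' Instantiate an estimator from a specification and hyperparameters
#'
#' @param spec An [estimator_spec()].
#' @param hyperparams Named list; must lie inside the declared search space.
#'   Fixed settings fill in anything not searched over.
#' @return An unfitted `evx_estimator`; fit with [fit_estimator()].
#' @export
make_estimator <- function(spec, hyperparams = list()) {
  stopifnot(inherits(spec, "estimator_spec"))
  check_in_space(spec$space, hyperparams)
  hp <- spec$fixed
  hp[names(hyperparams)] <- hyperparams
  structure(list(spec = spec, hp = hp, fit = NULL),
            class = c(paste0("evx_", spec$family), "evx_estimator"))
}

#' Fit an estimator
#' @param est An `evx_estimator` from [make_estimator()].
#' @param x Numeric predictor matrix.
#' @param y Binary 0/1 labels.
#' @param seed Integer seed (stochastic families).
#' @return The fitted estimator.
#' @export
fit_estimator <- function(est, x, y, seed = 1L) UseMethod("fit_estimator")

#' Predict class-1 probabilities
#' @param est A fitted `evx_estimator`.
#' @param x Numeric predictor matrix.
#' @return Numeric vector of probabilities.
#' @export
predict_proba <- function(est, x) UseMethod("predict_proba")

#' Number of fitted parameters (reporting only; the BIC complexity term uses
#' the number of selected features)
#' @inheritParams predict_proba
#' @export
parameter_count <- function(est) UseMethod("parameter_count")

#' Family-inherent feature importance
#'
#' Trees: gain. Logistic: absolute coefficient. Neural nets have no inherent
#' measure and return `NULL` (use [permutation_importance()]).
#' @inheritParams predict_proba
#' @return Named numeric vector, or `NULL`.
#' @export
inherent_importance <- function(est) UseMethod("inherent_importance")

#' @export
fit_estimator.evx_logistic_elasticnet <- function(est, x, y, seed = 1L) {
  x <- as.matrix(x)
  est$fit <- glmnet::glmnet(x, factor(y, levels = c(0, 1)),
                            family = "binomial",
                            alpha = est$hp$mixing, lambda = est$hp$strength,
                            standardize = TRUE)
  est$features <- colnames(x)
  est
}

#' @export
predict_proba.evx_logistic_elasticnet <- function(est, x) {
  as.numeric(stats::predict(est$fit, as.matrix(x), type = "response"))
}

#' @export
parameter_count.evx_logistic_elasticnet <- function(est) {
  length(est$features) + 1L
}

#' @export
inherent_importance.evx_logistic_elasticnet <- function(est) {
  b <- as.numeric(stats::coef(est$fit))[-1]
  stats::setNames(abs(b), est$features)
}

#' @export
fit_estimator.evx_boosted_trees <- function(est, x, y, seed = 1L) {
  x <- as.matrix(x)
  dtrain <- xgboost::xgb.DMatrix(data = x, label = y)
  params <- list(
    objective = "binary:logistic", booster = "gbtree",
    eta = est$hp$eta, max_depth = as.integer(est$hp$max_depth),
    subsample = est$hp$subsample, colsample_bytree = est$hp$colsample,
    lambda = est$hp$lambda, gamma = est$hp$gamma,
    nthread = 1, seed = as.integer(seed)
  )
  est$fit <- with_seed(seed, {
    xgboost::xgb.train(params = params, data = dtrain,
                       nrounds = as.integer(est$hp$n_estimators), verbose = 0)
  })
  est$features <- colnames(x)
  est
}

#' @export
predict_proba.evx_boosted_trees <- function(est, x) {
  stats::predict(est$fit, xgboost::xgb.DMatrix(data = as.matrix(x)))
}

#' @export
parameter_count.evx_boosted_trees <- function(est) {
  as.integer(est$hp$n_estimators)
}

#' @export
inherent_importance.evx_boosted_trees <- function(est) {
  imp <- stats::setNames(rep(0, length(est$features)), est$features)
  tab <- tryCatch(xgboost::xgb.importance(model = est$fit), error = function(e) NULL)
  if (!is.null(tab) && nrow(tab)) imp[tab$Feature] <- tab$Gain
  imp
}

#' @export
fit_estimator.evx_neural_net <- function(est, x, y, seed = 1L) {
  est$fit <- mlp_train(
    x, y, hidden = est$hp$hidden, lr = est$hp$learning_rate,
    batch_size = as.integer(est$hp$batch_size),
    epochs = as.integer(est$hp$epochs), patience = est$hp$patience,
    val_fraction = est$hp$val_fraction, seed = seed
  )
  est$features <- colnames(as.matrix(x))
  est
}

#' @export
predict_proba.evx_neural_net <- function(est, x) {
  mlp_predict_proba(est$fit, x)
}

#' @export
parameter_count.evx_neural_net <- function(est) {
  sizes <- est$fit$sizes
  sum(sizes[-length(sizes)] * sizes[-1] + sizes[-1])
}

#' @export
inherent_importance.evx_neural_net <- function(est) NULL

#' Build a stratified cross-validation plan
#'
#' The fold count adapts to model complexity: `k` is the nearest integer
#' strictly above `n / p` (integer ratios round up by one), optionally
#' capped. If `k` exceeds the minority class count it falls back to that
#' count with a warning so every fold can contain both classes.
#'
#' @param n Sample count.
#' @param p Number of selected features.
#' @param labels Binary 0/1 labels (length `n`).
#' @param cap Optional maximum fold count.
#' @param seed Integer seed for the fold shuffle.
#' @return A `cv_plan`: list with `k` and `folds` (fold id per observation).
#' @export
build_cv_plan <- function(n, p, labels, cap = NULL, seed = 1L) {
  stopifnot(n >= 2, p >= 1)
  ratio <- n / p
  k <- if (abs(ratio - round(ratio)) < 1e-9) as.integer(round(ratio)) + 1L
       else as.integer(ceiling(ratio))
  if (!is.null(cap)) k <- min(k, as.integer(cap))
  minority <- min(table(factor(labels, levels = c(0, 1))))
  if (k > minority && minority >= 2) {
    warning(sprintf("build_cv_plan: k=%d exceeds minority count; using k=%d",
                    k, minority))
    k <- as.integer(minority)
  }
  k <- max(k, 2L)
  folds <- integer(n)
  with_seed(substream_seed(seed, "cvplan"), {
    for (cl in unique(labels)) {
      idx <- resample(which(labels == cl))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  structure(list(k = k, folds = folds), class = "cv_plan")
}

#' Cross-validated fit of one chromosome: the BIC fitness record
#'
#' Fits the estimator on each training fold and scores the held-out fold;
#' the summed out-of-fold binomial log-likelihood enters the fitness
#' `bic = p * log(n) - 2 * loglik` with `p` the number of selected features.
#' Folds whose training part is single-class are skipped with a warning.
#'
#' @param spec An [estimator_spec()].
#' @param hyperparams Named list within the search space.
#' @param x Full predictor matrix (training partition).
#' @param y Binary labels.
#' @param feature_subset Integer (or name) indices of the selected features.
#' @param seed Seed for stochastic estimator fits.
#' @param cap Fold-count cap passed to [build_cv_plan()].
#' @param plan_seed Seed for the fold assignment; keep constant across
#'   chromosomes of one run so equal-sized subsets share folds.
#' @param prob_floor Probability floor in the log-likelihood.
#' @return A `fitness_record`: chromosome, `n`, `p`, `loglik`, `bic`,
#'   per-fold metrics, mean inherent importances.
#' @export
cv_fit <- function(spec, hyperparams, x, y, feature_subset, seed = 1L,
                   cap = 10, plan_seed = seed, prob_floor = 1e-12) {
  x <- as.matrix(x)
  if (is.character(feature_subset)) {
    feature_subset <- match(feature_subset, colnames(x))
  }
  stopifnot(length(feature_subset) >= 1,
            all(feature_subset >= 1 & feature_subset <= ncol(x)))
  p <- length(feature_subset)
  n <- nrow(x)
  xs <- x[, feature_subset, drop = FALSE]
  plan <- build_cv_plan(n, p, y, cap = cap, seed = plan_seed)
  loglik <- 0
  n_scored <- 0L
  fold_rows <- list()
  imp_sum <- NULL
  skipped <- 0L
  for (f in seq_len(plan$k)) {
    tr <- plan$folds != f
    va <- !tr
    if (length(unique(y[tr])) < 2 || !any(va)) {
      skipped <- skipped + 1L
      next
    }
    est <- make_estimator(spec, hyperparams)
    est <- fit_estimator(est, xs[tr, , drop = FALSE], y[tr],
                         seed = substream_seed(seed, paste0("fold", f)))
    pr <- predict_proba(est, xs[va, , drop = FALSE])
    loglik <- loglik + binomial_loglik(pr, y[va], floor = prob_floor)
    n_scored <- n_scored + sum(va)
    pred <- as.integer(pr >= 0.5)
    fold_rows[[length(fold_rows) + 1L]] <- tibble::tibble(
      fold = f,
      accuracy = mean(pred == y[va]),
      log_loss = -binomial_loglik(pr, y[va], floor = prob_floor) / sum(va)
    )
    imp <- inherent_importance(est)
    if (!is.null(imp)) {
      if (is.null(imp_sum)) imp_sum <- imp * 0
      imp_sum <- imp_sum + imp
    }
  }
  if (skipped > 0) {
    warning(sprintf("cv_fit: %d degenerate fold(s) skipped", skipped))
  }
  if (n_scored == 0L) stop("cv_fit: no valid folds")
  n_folds_used <- plan$k - skipped
  structure(
    list(
      chromosome = list(hyperparams = hyperparams,
                        subset = sort(feature_subset)),
      n = n_scored, p = p, loglik = loglik,
      bic = bic_fitness(loglik, n_scored, p),
      fold_metrics = dplyr::bind_rows(fold_rows),
      importances = if (!is.null(imp_sum)) imp_sum / n_folds_used else NULL,
      k = plan$k
    ),
    class = "fitness_record"
  )
}

#' @export
print.fitness_record <- function(x, ...) {
  cat(sprintf("<fitness_record> p=%d n=%d loglik=%.2f BIC=%.2f\n",
              x$p, x$n, x$loglik, x$bic))
  invisible(x)
}
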