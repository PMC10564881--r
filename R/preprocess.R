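#' Drop features with excessive missingness
#'
#' Features whose missing fraction exceeds `max_missing` are discarded
#' (strictly greater than the threshold: a feature at exactly the threshold
#' is retained).
#'
#' @param table A `feature_table`.
#' @param max_missing Maximum tolerated missing fraction, in (0,1).
#' @return The filtered `feature_table`, with the dropped feature names in
#'   `attr(, "dropped")`.
#' @export
drop_sparse_features <- function(table, max_missing = 0.40) {
  stopifnot(max_missing > 0, max_missing < 1)
  miss <- colMeans(!table$mask)
  keep <- miss <= max_missing
  if (!any(keep)) stop("drop_sparse_features: all features exceed the missingness threshold")
  out <- ft_subset(table, cols = which(keep))
  attr(out, "dropped") <- colnames(table$values)[!keep]
  out
}

#' Trim outliers to mean +/- k standard deviations
#'
#' Observed values of each continuous feature are clipped into
#' `[mean - k_sd * sd, mean + k_sd * sd]`, with the mean and sd computed on
#' the observed entries of the same partition. Constant (zero-variance)
#' features are left unchanged with a warning.
#'
#' @param table A `feature_table`.
#' @param k_sd Number of standard deviations, default 3.
#' @return The trimmed `feature_table`.
#' @export
trim_outliers <- function(table, k_sd = 3) {
  vals <- table$values
  cont <- table$meta$type == "continuous"
  constant <- character()
  for (j in which(cont)) {
    obs <- table$mask[, j]
    x <- vals[obs, j]
    if (length(x) < 2) next
    s <- stats::sd(x)
    if (is.na(s) || s == 0) {
      constant <- c(constant, colnames(vals)[j])
      next
    }
    m <- mean(x)
    vals[obs, j] <- pmin(pmax(x, m - k_sd * s), m + k_sd * s)
  }
  if (length(constant)) {
    warning("trim_outliers: constant features left unchanged: ",
            paste(constant, collapse = ", "))
  }
  ft_replace_values(table, vals)
}

# Masked non-negative matrix factorization by multiplicative updates.
# Minimizes sum over observed cells of (x - WH)^2; the classical
# mask-weighted update rules make this objective non-increasing.
nnmf_engine <- function(x, mask, rank, max_iter, tol, seed, h_fixed = NULL) {
  n <- nrow(x); p <- ncol(x)
  eps <- 1e-10
  xm <- x
  xm[!mask] <- 0
  with_seed(seed, {
    w <- matrix(stats::runif(n * rank, 0.1, 1), n, rank)
    h <- if (is.null(h_fixed)) {
      matrix(stats::runif(rank * p, 0.1, 1), rank, p)
    } else {
      h_fixed
    }
    obj <- numeric(0)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      wh <- w %*% h
      w <- w * ((xm %*% t(h)) / ((mask * wh) %*% t(h) + eps))
      if (is.null(h_fixed)) {
        wh <- w %*% h
        h <- h * ((t(w) %*% xm) / (t(w) %*% (mask * wh) + eps))
      }
      wh <- w %*% h
      obj <- c(obj, sum(((x - wh)[mask])^2))
      if (it > 1 && (obj[it - 1] - obj[it]) <= tol * max(obj[it - 1], eps)) {
        converged <- TRUE
        break
      }
    }
    list(w = w, h = h, objective = obj, converged = converged)
  })
}

#' Impute missing cells with masked non-negative matrix factorization
#'
#' Values are shifted to be non-negative (the offset is recorded and undone),
#' a rank-`rank` factorization is fitted by multiplicative updates that
#' minimize squared error over observed cells only, and only the cells with
#' `mask = FALSE` are replaced by the reconstruction. Observed entries are
#' returned bit-identical.
#'
#' @param table A `feature_table`.
#' @param rank Factorization rank (>= 1).
#' @param max_iter Maximum multiplicative-update iterations.
#' @param tol Relative objective-decrease tolerance for convergence.
#' @param seed Seed for the factor initialization.
#' @return The imputed `feature_table` (mask all-`TRUE`), with the fitted
#'   model in `attr(, "nnmf")` (`w`, `h`, `offset`, `objective` trace).
#' @export
impute_nnmf <- function(table, rank = 10, max_iter = 500, tol = 1e-5, seed = 1L) {
  stopifnot(rank >= 1)
  if (all(table$mask)) {
    out <- table
    attr(out, "nnmf") <- NULL
    return(out)
  }
  vals <- table$values
  obs_min <- min(vals[table$mask])
  offset <- if (obs_min < 0) -obs_min else 0
  x <- vals + offset
  x[!table$mask] <- 0
  fit <- nnmf_engine(x, table$mask, rank, max_iter, tol,
                     substream_seed(seed, "nnmf"))
  if (!fit$converged) {
    warning("impute_nnmf: multiplicative updates did not converge in ",
            max_iter, " iterations; returning best iterate")
  }
  recon <- fit$w %*% fit$h - offset
  out_vals <- vals
  out_vals[!table$mask] <- recon[!table$mask]
  out <- feature_table(out_vals, matrix(TRUE, nrow(vals), ncol(vals)),
                       table$meta, table$subject_ids)
  attr(out, "nnmf") <- list(w = fit$w, h = fit$h, offset = offset,
                            rank = rank, objective = fit$objective)
  out
}

# Impute a new partition against a previously fitted feature basis: the
# subject factors are refit with H held fixed, so no statistic of the new
# partition leaks into the fitted model.
nnmf_impute_with_basis <- function(table, basis, max_iter = 500, tol = 1e-5,
                                   seed = 1L) {
  if (all(table$mask)) return(table)
  vals <- table$values
  x <- vals + basis$offset
  x[!table$mask] <- 0
  fit <- nnmf_engine(x, table$mask, basis$rank, max_iter, tol,
                     substream_seed(seed, "nnmf_apply"), h_fixed = basis$h)
  recon <- fit$w %*% basis$h - basis$offset
  out_vals <- vals
  out_vals[!table$mask] <- recon[!table$mask]
  feature_table(out_vals, matrix(TRUE, nrow(vals), ncol(vals)),
                table$meta, table$subject_ids)
}

#' Agglomerate related items into a single summary score
#'
#' Columns are merged hierarchically (Ward linkage on Euclidean column
#' distance) down to one cluster; the summary score of the final cluster is
#' the mean over its leaf columns, so the full agglomeration equals the
#' per-subject mean of all items. The merge order is recorded for provenance.
#'
#' @param items Numeric matrix or data frame of related columns (no missing
#'   entries).
#' @return Numeric summary score per subject, with the merge tree (if more
#'   than one column) in `attr(, "merge")` and the item names in
#'   `attr(, "items")`.
#' @export
agglomerate_items <- function(items) {
  m <- as.matrix(items)
  stopifnot(ncol(m) >= 1, !anyNA(m))
  if (ncol(m) == 1) {
    score <- m[, 1]
    attr(score, "items") <- colnames(m)
    return(score)
  }
  hc <- stats::hclust(stats::dist(t(m)), method = "ward.D2")
  score <- rowMeans(m)
  attr(score, "merge") <- hc$merge
  attr(score, "items") <- colnames(m)
  score
}

#' Min-max scale features on the training partition
#'
#' Learns the per-feature affine map sending the training minimum to 0 and
#' maximum to 1. Apply the returned map to the test partition with
#' [apply_minmax()]; test values may legitimately fall outside \[0, 1\]
#' (no clipping). Constant features map to 0.
#'
#' @param table An imputed (complete) `feature_table`.
#' @return The scaled `feature_table`, with the fitted map (`min`, `range`,
#'   `constant`) in `attr(, "minmax")`.
#' @export
scale_minmax <- function(table) {
  vals <- table$values
  mins <- apply(vals, 2, min)
  maxs <- apply(vals, 2, max)
  rng <- maxs - mins
  constant <- rng == 0
  rng[constant] <- 1
  out <- ft_replace_values(table, sweep(sweep(vals, 2, mins), 2, rng, "/"))
  attr(out, "minmax") <- list(min = mins, range = rng, constant = constant)
  out
}

#' Apply a fitted min-max map to another partition
#'
#' @param table A complete `feature_table` with the same features.
#' @param map The `minmax` attribute produced by [scale_minmax()].
#' @return The affinely mapped `feature_table`.
#' @export
apply_minmax <- function(table, map) {
  stopifnot(identical(colnames(table$values), names(map$min)))
  ft_replace_values(
    table, sweep(sweep(table$values, 2, map$min), 2, map$range, "/")
  )
}

# Yeo-Johnson power transform and its profile-likelihood lambda.
yeo_johnson <- function(x, lambda) {
  out <- numeric(length(x))
  pos <- x >= 0
  if (abs(lambda) > 1e-8) {
    out[pos] <- ((x[pos] + 1)^lambda - 1) / lambda
  } else {
    out[pos] <- log1p(x[pos])
  }
  if (abs(lambda - 2) > 1e-8) {
    out[!pos] <- -((1 - x[!pos])^(2 - lambda) - 1) / (2 - lambda)
  } else {
    out[!pos] <- -log1p(-x[!pos])
  }
  out
}

yj_fit_lambda <- function(x) {
  ll <- function(lambda) {
    y <- yeo_johnson(x, lambda)
    s2 <- stats::var(y) * (length(y) - 1) / length(y)
    if (!is.finite(s2) || s2 <= 0) return(-Inf)
    -length(x) / 2 * log(s2) + (lambda - 1) * sum(sign(x) * log1p(abs(x)))
  }
  stats::optimize(ll, c(-3, 3), maximum = TRUE)$maximum
}

# Rank-based quantile-to-normal map (Blom offsets); new data are mapped
# through the training empirical quantiles.
quantile_normal_fit <- function(x) {
  n <- length(x)
  list(sorted = sort(x), n = n)
}

quantile_normal_apply <- function(x, fit) {
  # fractional rank of x within the training sample, Blom-adjusted
  r <- (findInterval(x, fit$sorted) + 0.5 - 0.375) / (fit$n + 0.25)
  stats::qnorm(pmin(pmax(r, 1e-6), 1 - 1e-6))
}

ad_statistic <- function(x) {
  if (stats::sd(x) < 1e-12) return(Inf)
  unname(nortest::ad.test(x)$statistic)
}

#' Select the normalizing transform for a continuous feature
#'
#' Compares the untransformed column against a Yeo-Johnson power transform
#' (maximum-likelihood lambda) and a rank-based quantile-to-normal map, using
#' the Anderson-Darling statistic on standardized values. A column that
#' already passes Anderson-Darling normality at alpha = 0.05 is kept
#' untransformed; otherwise the candidate with the smallest statistic wins,
#' with exact ties broken untransformed, then power, then quantile.
#'
#' @param x Numeric vector (continuous feature, n >= 20).
#' @return A list: `transformed` column, `report` (one-row tibble with the
#'   chosen transform and before/after statistics), and `transformer`
#'   (parameters to apply the same transform to new data via
#'   [apply_transform()]).
#' @export
select_normalizing_transform <- function(x) {
  stopifnot(length(x) >= 20)
  if (stats::sd(x) < 1e-12) {
    warning("select_normalizing_transform: constant column left unchanged")
    return(list(
      transformed = x,
      report = tibble::tibble(transform = "none", stat_before = NA_real_,
                              stat_after = NA_real_),
      transformer = list(kind = "none")
    ))
  }
  stat_none <- ad_statistic(x)
  p_none <- nortest::ad.test(x)$p.value
  lambda <- yj_fit_lambda(x)
  x_pow <- yeo_johnson(x, lambda)
  stat_pow <- ad_statistic(x_pow)
  qfit <- quantile_normal_fit(x)
  x_q <- quantile_normal_apply(x, qfit)
  stat_q <- ad_statistic(x_q)

  if (is.finite(p_none) && p_none > 0.05) {
    choice <- "none"
  } else {
    stats_all <- c(none = stat_none, power = stat_pow, quantile = stat_q)
    best <- min(stats_all)
    # preference order on exact ties: none, power, quantile
    choice <- names(stats_all)[which(stats_all <= best + 1e-12)][1]
  }
  out <- switch(choice, none = x, power = x_pow, quantile = x_q)
  list(
    transformed = out,
    report = tibble::tibble(
      transform = choice, stat_before = stat_none,
      stat_after = switch(choice, none = stat_none, power = stat_pow,
                          quantile = stat_q)
    ),
    transformer = switch(
      choice,
      none = list(kind = "none"),
      power = list(kind = "power", lambda = lambda),
      quantile = list(kind = "quantile", fit = qfit)
    )
  )
}

#' Apply a fitted normalizing transform to new data
#'
#' @param x Numeric vector.
#' @param transformer The `transformer` element returned by
#'   [select_normalizing_transform()].
#' @return The transformed vector.
#' @export
apply_transform <- function(x, transformer) {
  switch(transformer$kind,
         none = x,
         power = yeo_johnson(x, transformer$lambda),
         quantile = quantile_normal_apply(x, transformer$fit))
}

#' Build a binary case/not-case target from symptom items
#'
#' Symptom items are agglomerated into a single continuous severity score;
#' subjects with an exactly zero agglomerated score are labelled not-case
#' (0), everyone with any symptom burden is a case (1).
#'
#' @param symptom_items Non-negative numeric matrix or data frame of symptom
#'   item scores (complete; no missing entries).
#' @return A `binary_target`; if only one class results, a `single_class`
#'   attribute flags it (with a warning).
#' @export
binarize_target <- function(symptom_items) {
  m <- as.matrix(symptom_items)
  stopifnot(all(m >= 0), !anyNA(m))
  score <- agglomerate_items(m)
  labels <- as.integer(score > 0)
  out <- binary_target(labels, source_items = colnames(m))
  if (length(unique(labels)) < 2) {
    warning("binarize_target: target is single-class")
    attr(out, "single_class") <- TRUE
  }
  out
}

euclid_dist_rows <- function(a, b = a) {
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * a %*% t(b)
  sqrt(pmax(d2, 0))
}

#' Rebalance a training partition with SMOTE followed by ENN cleaning
#'
#' Synthetic minority rows are linear interpolations between a minority row
#' and one of its k nearest minority neighbours (oversampled to parity with
#' the majority class); edited-nearest-neighbour cleaning then removes any
#' row, from either class, whose label disagrees with the majority vote of
#' its `k_enn` nearest neighbours. Apply only to the training partition —
#' the class ratio can move past balance, and majority flips are possible.
#'
#' @param x Numeric matrix (or `feature_table`) of the training predictors.
#' @param target A `binary_target` for the same rows.
#' @param seed Integer seed.
#' @param k_smote Neighbour count for SMOTE interpolation (default 5;
#'   reduced with a warning when the minority class is smaller than k+1).
#' @param k_enn Neighbour count for the ENN vote (default 3).
#' @return A list with `x` (matrix), `target` (`binary_target`), and `info`,
#'   a tibble describing every candidate row (`origin`, SMOTE `parent_a`/
#'   `parent_b`/`gap`, and whether ENN `kept` it).
#' @export
resample_smoteenn <- function(x, target, seed = 1L, k_smote = 5, k_enn = 3) {
  if (inherits(x, "feature_table")) x <- x$values
  x <- as.matrix(x)
  y <- target$labels
  stopifnot(nrow(x) == length(y), length(unique(y)) == 2)
  minority <- as.integer(names(which.min(table(y))))
  n_min <- sum(y == minority)
  n_maj <- length(y) - n_min
  k <- k_smote
  if (n_min < k + 1) {
    k <- max(1L, n_min - 1L)
    warning(sprintf("resample_smoteenn: minority class has %d rows; reducing SMOTE k to %d",
                    n_min, k))
  }
  min_idx <- which(y == minority)
  xm <- x[min_idx, , drop = FALSE]
  n_synth <- max(0L, n_maj - n_min)
  synth <- with_seed(substream_seed(seed, "smote"), {
    if (n_synth == 0L) {
      list(rows = matrix(numeric(0), 0, ncol(x)), a = integer(0),
           b = integer(0), gap = numeric(0))
    } else {
      d <- euclid_dist_rows(xm)
      diag(d) <- Inf
      nn <- t(apply(d, 1, function(r) order(r)[seq_len(k)]))
      base <- sample.int(n_min, n_synth, replace = TRUE)
      pick <- sample.int(k, n_synth, replace = TRUE)
      gap <- stats::runif(n_synth)
      nb <- nn[cbind(base, pick)]
      rows <- xm[base, , drop = FALSE] +
        gap * (xm[nb, , drop = FALSE] - xm[base, , drop = FALSE])
      list(rows = rows, a = min_idx[base], b = min_idx[nb], gap = gap)
    }
  })
  x_all <- rbind(x, synth$rows)
  y_all <- c(y, rep(minority, nrow(synth$rows)))
  info <- tibble::tibble(
    origin = c(rep("original", nrow(x)), rep("synthetic", nrow(synth$rows))),
    label = y_all,
    parent_a = c(rep(NA_integer_, nrow(x)), synth$a),
    parent_b = c(rep(NA_integer_, nrow(x)), synth$b),
    gap = c(rep(NA_real_, nrow(x)), synth$gap)
  )
  # ENN: remove rows whose k_enn nearest neighbours out-vote their label
  d_all <- euclid_dist_rows(x_all)
  diag(d_all) <- Inf
  keep <- vapply(seq_len(nrow(x_all)), function(i) {
    nb <- order(d_all[i, ])[seq_len(min(k_enn, nrow(x_all) - 1))]
    votes <- y_all[nb]
    sum(votes == y_all[i]) >= length(votes) / 2
  }, logical(1))
  if (!any(keep)) stop("resample_smoteenn: ENN removed every row")
  info$kept <- keep
  y_out <- y_all[keep]
  if (length(unique(y_out)) < 2) {
    warning("resample_smoteenn: a class was emptied by ENN cleaning")
  }
  list(
    x = x_all[keep, , drop = FALSE],
    target = binary_target(y_all[keep], target$source_items),
    info = info
  )
}

#' Univariate odds ratio of a feature against a binary target
#'
#' Per-unit odds ratio from a single-predictor logistic fit with a Wald 95%
#' confidence interval. Features are assumed min-max scaled so per-unit odds
#' are comparable across predictors.
#'
#' @param feature Numeric vector.
#' @param target A `binary_target` (or 0/1 vector).
#' @return One-row tibble: `odds_ratio`, `ci_lower`, `ci_upper`, `p_value`,
#'   `diverged` (perfect-separation flag).
#' @export
univariate_odds_ratio <- function(feature, target) {
  y <- if (inherits(target, "binary_target")) target$labels else as.integer(target)
  diverged <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ feature, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        diverged <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  co <- summary(fit)$coefficients
  b <- co["feature", "Estimate"]
  se <- co["feature", "Std. Error"]
  if (abs(b) > 15) diverged <- TRUE
  tibble::tibble(
    odds_ratio = exp(b),
    ci_lower = exp(b - 1.96 * se),
    ci_upper = exp(b + 1.96 * se),
    p_value = co["feature", "Pr(>|z|)"],
    diverged = diverged
  )
}

#' Fit the preprocessing pipeline on the training partition
#'
#' Runs the preparation chain in fixed order — sparse-feature drop, outlier
#' trim, masked-NNMF imputation, min-max scaling, normalizing-transform
#' selection — learning every data-dependent parameter from the training
#' partition only. Apply the fitted pipeline to a test partition with
#' [prep_apply()].
#'
#' @param table Training `feature_table`.
#' @param max_missing Missingness threshold for [drop_sparse_features()].
#' @param k_sd Trim width for [trim_outliers()].
#' @param nnmf_rank,nnmf_max_iter,nnmf_tol Imputation settings.
#' @param select_transforms Whether to run per-feature normalizing-transform
#'   selection (the most expensive step).
#' @param seed Integer seed.
#' @return A `prep_pipeline` object; `$train` holds the fully prepared
#'   training `feature_table`, `$transform_report` the per-feature choices.
#' @export
prep_fit <- function(table, max_missing = 0.40, k_sd = 3, nnmf_rank = 10,
                     nnmf_max_iter = 500, nnmf_tol = 1e-5,
                     select_transforms = TRUE, seed = 1L) {
  dropped <- drop_sparse_features(table, max_missing)
  drop_list <- attr(dropped, "dropped")
  trimmed <- trim_outliers(dropped, k_sd)
  rank_use <- min(nnmf_rank, dim(trimmed)[1] - 1, dim(trimmed)[2] - 1)
  imputed <- impute_nnmf(trimmed, rank = rank_use, max_iter = nnmf_max_iter,
                         tol = nnmf_tol, seed = seed)
  nnmf_model <- attr(imputed, "nnmf")
  scaled <- scale_minmax(imputed)
  minmax <- attr(scaled, "minmax")
  transformers <- list()
  report <- NULL
  out <- scaled
  if (select_transforms) {
    vals <- scaled$values
    rows <- vector("list", ncol(vals))
    for (j in seq_len(ncol(vals))) {
      sel <- select_normalizing_transform(vals[, j])
      vals[, j] <- sel$transformed
      transformers[[colnames(vals)[j]]] <- sel$transformer
      rows[[j]] <- dplyr::mutate(sel$report, feature = colnames(vals)[j],
                                 .before = 1)
    }
    report <- dplyr::bind_rows(rows)
    out <- ft_replace_values(scaled, vals)
  }
  structure(
    list(train = out, dropped = drop_list, k_sd = k_sd,
         nnmf = nnmf_model, nnmf_settings = list(max_iter = nnmf_max_iter,
                                                 tol = nnmf_tol, seed = seed),
         minmax = minmax, transformers = transformers,
         transform_report = report, features = colnames(out$values)),
    class = "prep_pipeline"
  )
}

#' Apply a fitted preprocessing pipeline to a test partition
#'
#' The training-derived drop list, NNMF feature basis, min-max map and
#' transform choices are applied unchanged; outlier trimming uses the test
#' partition's own moments (trim bounds are a per-partition operation, not a
#' fitted parameter).
#'
#' @param prep A `prep_pipeline` from [prep_fit()].
#' @param table Test `feature_table` with the same original features.
#' @return The prepared test `feature_table`.
#' @export
prep_apply <- function(prep, table) {
  keep <- setdiff(colnames(table$values), prep$dropped)
  out <- ft_subset(table, cols = keep)
  out <- trim_outliers(out, prep$k_sd)
  if (!is.null(prep$nnmf)) {
    out <- nnmf_impute_with_basis(out, prep$nnmf,
                                  max_iter = prep$nnmf_settings$max_iter,
                                  tol = prep$nnmf_settings$tol,
                                  seed = prep$nnmf_settings$seed)
  } else if (!all(out$mask)) {
    stop("prep_apply: test partition has missing cells but no imputation model was fitted")
  }
  out <- apply_minmax(out, prep$minmax)
  if (length(prep$transformers)) {
    vals <- out$values
    for (nm in names(prep$transformers)) {
      vals[, nm] <- apply_transform(vals[, nm], prep$transformers[[nm]])
    }
    out <- ft_replace_values(out, vals)
  }
  out
}
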