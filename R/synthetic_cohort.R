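#' Specify a synthetic multidomain cohort
#'
#' Describes a cohort with the statistical structure the pipeline assumes:
#' mixed-domain predictors with non-normal marginals and a shared low-rank
#' latent structure, planted informative feature subsets with linear and
#' non-linear effects, class imbalance, and controllable missingness. The
#' defaults emulate a community mental-health cohort of ~1120 subjects with
#' 160 candidate predictors.
#'
#' @param n_subjects Number of subjects.
#' @param n_features Number of candidate predictors.
#' @param domain_blocks Named integer vector of block sizes summing to
#'   `n_features` (e.g. `c(psychosocial = 100, cognitive = 30, neural = 30)`).
#'   `NULL` = one block.
#' @param informative Per-target list. Each target is a data frame with
#'   columns `feature` (index), `type` (`"linear"`, `"interaction"`,
#'   `"threshold"`), `size` (standardized effect size) and optionally
#'   `partner` (second feature index for interactions; defaults to
#'   `feature + 1`).
#' @param case_rate Named numeric vector of target case proportions in (0,1),
#'   aligned with `informative`.
#' @param missing_rate Overall proportion of missing cells, in \[0, 0.6\].
#' @param missing_mechanism `"MCAR"` or `"MAR"`. Under MAR the missingness
#'   probability of each feature is logistic in one fully observed driver
#'   feature per domain block.
#' @param marginal_family `"normal"`, `"lognormal"` or `"skewed_mixture"`
#'   marginals for the predictors.
#' @param latent_rank Rank of the shared latent structure (for imputation
#'   tests); must be below `min(n_subjects, n_features)`.
#' @param noise_sd Standard deviation of the feature-specific noise added to
#'   the latent structure before marginal transformation.
#' @param seed Master seed; all generator randomness derives from it.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects = 1120,
                        n_features = 160,
                        domain_blocks = NULL,
                        informative = list(),
                        case_rate = numeric(),
                        missing_rate = 0.15,
                        missing_mechanism = c("MCAR", "MAR"),
                        marginal_family = c("skewed_mixture", "normal", "lognormal"),
                        latent_rank = 8,
                        noise_sd = 1,
                        seed = 1L) {
  missing_mechanism <- match.arg(missing_mechanism)
  marginal_family <- match.arg(marginal_family)
  if (is.null(domain_blocks)) domain_blocks <- c(all = n_features)
  stopifnot(
    sum(domain_blocks) == n_features,
    missing_rate >= 0, missing_rate <= 0.6,
    latent_rank >= 1, latent_rank < min(n_subjects, n_features),
    length(informative) == length(case_rate)
  )
  if (length(case_rate)) {
    stopifnot(all(case_rate > 0 & case_rate < 1))
    if (is.null(names(case_rate))) {
      names(case_rate) <- sprintf("target%d", seq_along(case_rate))
    }
    if (is.null(names(informative))) names(informative) <- names(case_rate)
    for (tg in names(informative)) {
      inf <- informative[[tg]]
      if (nrow(inf)) {
        stopifnot(
          !anyDuplicated(inf$feature),
          all(inf$feature >= 1 & inf$feature <= n_features),
          all(inf$type %in% c("linear", "interaction", "threshold"))
        )
      }
    }
  }
  structure(
    list(n_subjects = n_subjects, n_features = n_features,
         domain_blocks = domain_blocks, informative = informative,
         case_rate = case_rate, missing_rate = missing_rate,
         missing_mechanism = missing_mechanism,
         marginal_family = marginal_family, latent_rank = latent_rank,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# Raw generating score for one target on the standardized latent features.
planted_score <- function(z, inf) {
  score <- numeric(nrow(z))
  if (!nrow(inf)) return(score)
  if (is.null(inf$partner)) inf$partner <- NA_integer_
  for (i in seq_len(nrow(inf))) {
    j <- inf$feature[i]
    b <- inf$size[i]
    score <- score + switch(
      inf$type[i],
      linear = b * z[, j],
      interaction = {
        k <- inf$partner[i]
        if (is.na(k)) k <- if (j < ncol(z)) j + 1L else 1L
        b * z[, j] * z[, k]
      },
      threshold = b * (z[, j] > stats::quantile(z[, j], 0.70))
    )
  }
  score
}

#' Generate a synthetic cohort with planted signal
#'
#' Draws a shared low-rank Gaussian latent structure, maps it through the
#' requested marginal family (a Gaussian-copula construction: marginals are
#' monotone transforms of latent normals, so dependence is controlled
#' separately from shape), plants target signal on the standardized latent
#' features, samples labels from a logistic model whose intercept is
#' calibrated to the requested case rate, and finally applies the missingness
#' mechanism.
#'
#' @param spec A [cohort_spec()].
#' @return A list with components:
#'   * `table` — the masked `feature_table` (what an analyst would see),
#'   * `table_complete` — the same table before missingness,
#'   * `targets` — named list of `binary_target`s,
#'   * `ground_truth` — informative indices, Bayes-optimal class
#'     probabilities, empirical Bayes AUC per target, and the missingness
#'     mechanism actually applied.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  p <- spec$n_features
  with_seed(substream_seed(spec$seed, "cohort"), {
    # low-rank latent structure + feature noise
    u <- matrix(stats::rnorm(n * spec$latent_rank), n, spec$latent_rank)
    v <- matrix(stats::rnorm(p * spec$latent_rank), spec$latent_rank, p)
    latent <- u %*% v + spec$noise_sd * matrix(stats::rnorm(n * p), n, p)
    z <- scale(latent)  # standardized latent features drive the signal

    vals <- switch(
      spec$marginal_family,
      normal = z,
      lognormal = exp(z),
      skewed_mixture = {
        # monotone transform of the latent normal: squared-exponential tail
        # mixed with the identity produces right-skew + heavy tails
        0.6 * z + 0.4 * (exp(z / 1.5) - 1) * 1.5
      }
    )
    domains <- rep(names(spec$domain_blocks), spec$domain_blocks)
    meta <- tibble::tibble(
      name = sprintf("f%03d", seq_len(p)), domain = domains,
      type = "continuous"
    )
    colnames(vals) <- meta$name
    complete <- feature_table(vals, meta = meta)

    targets <- list()
    gt_targets <- list()
    for (tg in names(spec$case_rate)) {
      inf <- spec$informative[[tg]]
      score <- planted_score(z, inf)
      rate <- spec$case_rate[[tg]]
      if (stats::sd(score) < 1e-12) {
        alpha <- stats::qlogis(rate)
      } else {
        f <- function(a) mean(stats::plogis(a + score)) - rate
        lo <- -50; hi <- 50
        if (f(lo) > 0 || f(hi) < 0) {
          stop(sprintf(
            "generate_cohort: case_rate %.3f unreachable for target '%s' with the requested effects",
            rate, tg
          ))
        }
        alpha <- stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
      }
      prob <- stats::plogis(alpha + score)
      labels <- stats::rbinom(n, 1, prob)
      bayes_auc <- if (stats::sd(prob) < 1e-12 || length(unique(labels)) < 2) {
        0.5
      } else {
        roc_auc(prob, labels)$auc
      }
      targets[[tg]] <- binary_target(labels, source_items = character())
      gt_targets[[tg]] <- list(
        informative = inf, intercept = alpha, bayes_prob = prob,
        bayes_auc = bayes_auc, case_rate_requested = rate
      )
    }

    mask <- apply_missingness(vals, domains, spec)
    masked <- feature_table(vals, mask, meta)
    list(
      table = masked,
      table_complete = complete,
      targets = targets,
      ground_truth = list(
        targets = gt_targets,
        missing_mechanism = spec$missing_mechanism,
        missing_rate = spec$missing_rate,
        latent_rank = spec$latent_rank
      )
    )
  })
}

# Missingness mask (TRUE = observed). MCAR: uniform. MAR: the first feature
# of each domain block stays fully observed and drives the missingness odds
# of the other features in its block.
apply_missingness <- function(vals, domains, spec) {
  n <- nrow(vals); p <- ncol(vals)
  mask <- matrix(TRUE, n, p)
  if (spec$missing_rate <= 0) return(mask)
  if (spec$missing_mechanism == "MCAR") {
    mask <- matrix(stats::runif(n * p) >= spec$missing_rate, n, p)
  } else {
    slope <- 1.5
    for (dom in unique(domains)) {
      cols <- which(domains == dom)
      driver <- cols[1]
      targets <- setdiff(cols, driver)
      if (!length(targets)) next
      x <- scale(vals[, driver])[, 1]
      # calibrate intercept so block-average missingness matches the spec
      # (drivers are fully observed, so inflate the per-feature rate)
      rate_t <- min(0.95, spec$missing_rate * length(cols) / length(targets))
      g <- function(a) mean(stats::plogis(a + slope * x)) - rate_t
      a <- stats::uniroot(g, c(-30, 30), tol = 1e-9)$root
      pm <- stats::plogis(a + slope * x)
      for (j in targets) mask[, j] <- stats::runif(n) >= pm
    }
  }
  mask
}

#' Split a cohort into train and test partitions
#'
#' Unstratified random row split, mirroring a 70/30 train/test reservation
#' (1120 subjects give 784 train / 336 test at the default fraction).
#'
#' @param table A `feature_table`.
#' @param targets Named list of `binary_target`s (may be empty).
#' @param train_fraction Proportion of rows assigned to training, in (0,1).
#' @param seed Integer seed; identical seeds give identical partitions.
#' @return A list with `train` / `test`, each holding `table`, `targets`,
#'   and the row `indices` into the input.
#' @export
split_cohort <- function(table, targets = list(), train_fraction = 0.7, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  n <- nrow(table$values)
  n_train <- round(n * train_fraction)
  if (n_train == 0 || n_train == n) {
    stop("split_cohort: a partition would be empty")
  }
  idx <- with_seed(substream_seed(seed, "split"), sample.int(n, n_train))
  idx <- sort(idx)
  test_idx <- setdiff(seq_len(n), idx)
  part <- function(rows) {
    list(
      table = ft_subset(table, rows = rows),
      targets = lapply(targets, function(t) {
        binary_target(t$labels[rows], t$source_items)
      }),
      indices = rows
    )
  }
  list(train = part(idx), test = part(test_idx))
}

#' Generate synthetic component timecourses with planted connectivity states
#'
#' Each subject's timecourse is a components x timepoints matrix. Time is
#' divided into consecutive windows of `window_length` points; each window is
#' drawn i.i.d. from a zero-mean Gaussian whose correlation matrix is the
#' planted state assigned to that window, so per-window sample correlations
#' concentrate around their generating centroid.
#'
#' @param n_subjects Number of subjects.
#' @param n_components Number of components per subject.
#' @param state_spec A list with `centroids` (list of valid correlation
#'   matrices: symmetric, unit diagonal, positive semi-definite) and
#'   `labels` (integer vector of per-window generating states, shared across
#'   subjects).
#' @param window_length Timepoints per planted window.
#' @param sampling_interval Seconds per timepoint (metadata only).
#' @param seed Master seed.
#' @return A `timecourse_set`: list of per-subject matrices plus the planted
#'   truth (`centroids`, per-window `labels`, true switch count).
#' @export
generate_timecourses <- function(n_subjects, n_components, state_spec,
                                 window_length = 30, sampling_interval = 1.5,
                                 seed = 1L) {
  cents <- state_spec$centroids
  labels <- as.integer(state_spec$labels)
  stopifnot(length(cents) >= 1, all(labels >= 1), all(labels <= length(cents)))
  chols <- lapply(seq_along(cents), function(i) {
    s <- cents[[i]]
    if (!isSymmetric(unname(s)) || any(abs(diag(s) - 1) > 1e-8)) {
      stop(sprintf("generate_timecourses: centroid %d is not a correlation matrix", i))
    }
    ev <- eigen(s, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) {
      stop(sprintf("generate_timecourses: centroid %d is not positive semi-definite", i))
    }
    chol(s + diag(1e-10, nrow(s)))
  })
  n_win <- length(labels)
  t_total <- n_win * window_length
  if (t_total < 2 * window_length) {
    stop("generate_timecourses: need at least two windows of timepoints")
  }
  subjects <- with_seed(substream_seed(seed, "timecourses"), {
    lapply(seq_len(n_subjects), function(s) {
      tc <- matrix(0, n_components, t_total)
      for (w in seq_len(n_win)) {
        z <- matrix(stats::rnorm(n_components * window_length),
                    window_length, n_components)
        block <- t(z %*% chols[[labels[w]]])
        tc[, ((w - 1) * window_length + 1):(w * window_length)] <- block
      }
      tc
    })
  })
  true_switches <- sum(diff(labels) != 0)
  structure(
    list(subjects = subjects, sampling_interval = sampling_interval,
         planted = list(centroids = cents, labels = labels,
                        window_length = window_length,
                        n_switches = true_switches)),
    class = "timecourse_set"
  )
}

#' @export
print.timecourse_set <- function(x, ...) {
  cat(sprintf("<timecourse_set> %d subjects, %d components x %d timepoints\n",
              length(x$subjects), nrow(x$subjects[[1]]), ncol(x$subjects[[1]])))
  invisible(x)
}
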