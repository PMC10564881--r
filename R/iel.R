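#' Evolution configuration
#'
#' Generation bookkeeping follows fixed proportions of the population size.
#' At the reference population of 100: the best 80 are kept, of which 40 are
#' recombined pairwise into 20 children, 20 are mutated, and 20 discarded;
#' 60 fresh random models top the next generation back up to 100. Donor
#' feature sets come from the best 60 models. After the warm restart the
#' population halves to 50, with 20 recombined children, 10 mutated and 20
#' fresh. Any population scales by the same proportions.
#'
#' @param population Models per generation in the main phase.
#' @param subset_range Bounds on the feature-subset size (default 2..50).
#' @param plateau_window,plateau_tol Plateau rule: stop when the relative
#'   improvement of best-so-far BIC over the last `plateau_window`
#'   generations falls below `plateau_tol`.
#' @param max_generations Hard cap on main-phase generations.
#' @param cv_cap Fold-count cap handed to [build_cv_plan()].
#' @param warm_start Run the importance-constrained recursive phase after
#'   the plateau.
#' @param warm_population Models per generation post warm start (default
#'   half the main population).
#' @param warm_max_generations Generation cap per warm phase.
#' @param sd_multipliers Escalating importance cutoffs: mean + m * SD.
#' @param importance_repeats Permutation-importance repeats used for the
#'   warm-start thresholds.
#' @param importance_donors Number of best records whose permutation
#'   importances are aggregated for the warm-start thresholds (the
#'   reference design uses the best-performing 60 models).
#' @param warm_recursions Maximum number of recursive warm-restart rounds
#'   (each re-aggregates importances and re-constrains the pool) before the
#'   SD-escalation phases.
#' @return An `evolution_config`.
#' @export
evolution_config <- function(population = 100,
                             subset_range = c(2, 50),
                             plateau_window = 10,
                             plateau_tol = 0.001,
                             max_generations = 100,
                             cv_cap = 10,
                             warm_start = TRUE,
                             warm_population = NULL,
                             warm_max_generations = 15,
                             sd_multipliers = 2:10,
                             importance_repeats = 5,
                             importance_donors = 60,
                             warm_recursions = 4) {
  if (is.null(warm_population)) warm_population <- max(4, round(population / 2))
  cfg <- list(
    population = population, subset_range = subset_range,
    plateau_window = plateau_window, plateau_tol = plateau_tol,
    max_generations = max_generations, cv_cap = cv_cap,
    warm_start = warm_start, warm_population = warm_population,
    warm_max_generations = warm_max_generations,
    sd_multipliers = sd_multipliers,
    importance_repeats = importance_repeats,
    importance_donors = importance_donors,
    warm_recursions = warm_recursions
  )
  cfg$counts <- generation_counts(population, warm = FALSE)
  cfg$warm_counts <- generation_counts(warm_population, warm = TRUE)
  structure(cfg, class = "evolution_config")
}

# Per-generation bookkeeping counts. Main-phase proportions (of population):
# 20% recombined children from 40% parents, 20% mutated, 80% "best" kept for
# breeding, 60% fresh, donors = 60%. Warm-phase proportions: 40% children
# from 80% parents, 20% mutated, 40% fresh.
generation_counts <- function(population, warm = FALSE) {
  p <- population
  if (!warm) {
    children <- round(0.2 * p); mutate <- round(0.2 * p)
    best <- round(0.8 * p); donors <- round(0.6 * p)
  } else {
    children <- round(0.4 * p); mutate <- round(0.2 * p)
    best <- 2 * children + mutate; donors <- round(0.6 * p)
  }
  parents <- 2L * children
  fresh <- p - children - mutate
  discard <- best - parents - mutate
  stopifnot(discard >= 0, fresh >= 0, parents + mutate + discard == best,
            children + mutate + fresh == p)
  list(population = p, n_best = best, n_parents = parents,
       n_children = children, n_mutate = mutate, n_discard = discard,
       n_fresh = fresh, n_donors = donors)
}

sample_hyperparams <- function(space) {
  hp <- list()
  for (i in seq_len(nrow(space))) {
    hp[[space$name[i]]] <- switch(
      space$type[i],
      real = if (space$log[i]) {
        exp(stats::runif(1, log(space$lower[i]), log(space$upper[i])))
      } else {
        stats::runif(1, space$lower[i], space$upper[i])
      },
      integer = resample(space$lower[i]:space$upper[i], 1),
      categorical = {
        ch <- space$choices[[i]]
        ch[[sample.int(length(ch), 1)]]
      }
    )
  }
  hp
}

random_chromosome <- function(space, pool, subset_range) {
  size <- resample(subset_range[1]:subset_range[2], 1)
  list(hyperparams = sample_hyperparams(space),
       subset = sort(resample(pool, size)))
}

#' Initialize a random population of chromosomes
#'
#' Hyperparameters are sampled uniformly in their declared bounds
#' (log-uniform where log-scaled); subset sizes are uniform on the declared
#' range, sampled without replacement from the feature pool.
#'
#' @param space A `search_space`.
#' @param config An [evolution_config()].
#' @param pool Integer vector of candidate feature indices.
#' @param seed Integer seed.
#' @param n Number of chromosomes (default `config$population`).
#' @return List of chromosomes (`hyperparams` + `subset`).
#' @export
init_population <- function(space, config, pool, seed = 1L, n = NULL) {
  if (is.null(n)) n <- config$population
  sr <- clamp_subset_range(config$subset_range, length(pool))
  with_seed(substream_seed(seed, "init"), {
    lapply(seq_len(n), function(i) random_chromosome(space, pool, sr))
  })
}

clamp_subset_range <- function(subset_range, pool_size) {
  sr <- subset_range
  if (sr[2] > pool_size) {
    warning(sprintf("feature pool (%d) smaller than max subset size (%d); shrinking",
                    pool_size, sr[2]))
    sr[2] <- pool_size
  }
  sr[1] <- min(sr[1], sr[2])
  sr
}

#' Recombine two parent chromosomes
#'
#' The hyperparameter vector (declared order) is split at the midpoint
#' pivot: genes before the pivot are copied from the first parent, genes
#' from the pivot on are set to the element-wise parent average (geometric
#' mean for log-scaled genes, rounded for integers, a seeded random parent
#' for categoricals). The child's feature subset is assigned separately by
#' [allocate_feature_sets()].
#'
#' @param parent_a,parent_b Chromosomes over the same search space.
#' @param space The `search_space`.
#' @param seed Seed for categorical gene choices.
#' @return A child chromosome (subset inherited from `parent_a` until
#'   reallocated).
#' @export
recombine <- function(parent_a, parent_b, space, seed = 1L) {
  d <- nrow(space)
  pivot <- floor(d / 2)
  hp <- parent_a$hyperparams
  with_seed(substream_seed(seed, "recombine"), {
    for (i in seq_len(d)) {
      if (i <= pivot) next
      nm <- space$name[i]
      a <- parent_a$hyperparams[[nm]]
      b <- parent_b$hyperparams[[nm]]
      hp[[nm]] <- switch(
        space$type[i],
        real = if (space$log[i]) exp((log(a) + log(b)) / 2) else (a + b) / 2,
        integer = as.integer(round((a + b) / 2)),
        categorical = if (stats::runif(1) < 0.5) a else b
      )
    }
  })
  list(hyperparams = hp, subset = parent_a$subset)
}

reflect_into <- function(x, lo, hi) {
  if (x > hi) x <- hi - (x - hi)
  if (x < lo) x <- lo + (lo - x)
  min(max(x, lo), hi)
}

#' Mutate one hyperparameter of a chromosome
#'
#' A single gene is chosen (seeded) and shifted by plus or minus its
#' declared mutation shift (log-space for log-scaled genes), reflecting at
#' the bounds. Categorical genes jump to another choice. The feature subset
#' is untouched.
#'
#' @param chromosome A chromosome.
#' @param space The `search_space`.
#' @param seed Integer seed.
#' @return The mutated chromosome.
#' @export
mutate_chromosome <- function(chromosome, space, seed = 1L) {
  with_seed(substream_seed(seed, "mutate"), {
    i <- sample.int(nrow(space), 1)
    nm <- space$name[i]
    v <- chromosome$hyperparams[[nm]]
    sgn <- if (stats::runif(1) < 0.5) -1 else 1
    chromosome$hyperparams[[nm]] <- switch(
      space$type[i],
      real = if (space$log[i]) {
        exp(reflect_into(log(v) + sgn * space$shift[i],
                         log(space$lower[i]), log(space$upper[i])))
      } else {
        reflect_into(v + sgn * space$shift[i], space$lower[i], space$upper[i])
      },
      integer = as.integer(round(reflect_into(v + sgn * space$shift[i],
                                              space$lower[i], space$upper[i]))),
      categorical = {
        ch <- space$choices[[i]]
        others <- ch[!vapply(ch, identical, logical(1), v)]
        if (length(others)) others[[sample.int(length(others), 1)]] else v
      }
    )
    chromosome
  })
}

#' Allocate donor feature sets to child chromosomes
#'
#' Donor subsets from the ranked best records are assigned in rank order:
#' the best donor's subset goes to the first child, and so on; surplus
#' donors are discarded. If there are fewer donors than children the
#' donors are recycled from the top with a warning.
#'
#' @param donor_records List of `fitness_record`s ranked by BIC (best
#'   first).
#' @param children List of child chromosomes.
#' @return The children with subsets replaced.
#' @export
allocate_feature_sets <- function(donor_records, children) {
  if (!length(children)) return(children)
  nd <- length(donor_records)
  if (nd < length(children)) {
    warning("allocate_feature_sets: fewer donors than children; recycling from the top")
  }
  for (i in seq_along(children)) {
    donor <- donor_records[[((i - 1) %% nd) + 1]]
    children[[i]]$subset <- donor$chromosome$subset
  }
  children
}

#' Breed the next generation from evaluated records
#'
#' Records are ranked ascending by BIC. The best block is split into
#' recombination parents (adjacent rank pairs), mutation sources, and
#' discards; recombined and mutated children receive donor feature sets in
#' rank order, and fresh random chromosomes fill the generation back to the
#' configured population size.
#'
#' @param records Evaluated `fitness_record`s of the current generation.
#' @param config An [evolution_config()].
#' @param space The `search_space`.
#' @param pool Candidate feature indices for fresh chromosomes.
#' @param seed Integer seed.
#' @param counts Bookkeeping counts (default main-phase counts).
#' @return List with `chromosomes` and `lineage`
#'   (`"recombined"`/`"mutated"`/`"fresh"`).
#' @export
step_generation <- function(records, config, space, pool, seed = 1L,
                            counts = config$counts) {
  stopifnot(length(records) >= counts$n_best)
  ord <- order(vapply(records, function(r) r$bic, numeric(1)))
  ranked <- records[ord]
  parents <- ranked[seq_len(counts$n_parents)]
  rec_children <- lapply(seq_len(counts$n_children), function(i) {
    recombine(parents[[2 * i - 1]]$chromosome, parents[[2 * i]]$chromosome,
              space, seed = substream_seed(seed, paste0("rc", i)))
  })
  mut_src <- ranked[counts$n_parents + seq_len(counts$n_mutate)]
  mut_children <- lapply(seq_along(mut_src), function(i) {
    mutate_chromosome(mut_src[[i]]$chromosome, space,
                      seed = substream_seed(seed, paste0("mu", i)))
  })
  children <- allocate_feature_sets(
    ranked[seq_len(min(counts$n_donors, length(ranked)))],
    c(rec_children, mut_children)
  )
  sr <- clamp_subset_range(config$subset_range, length(pool))
  fresh <- with_seed(substream_seed(seed, "fresh"), {
    lapply(seq_len(counts$n_fresh), function(i) {
      random_chromosome(space, pool, sr)
    })
  })
  out <- c(children, fresh)
  if (length(out) != counts$population) {
    stop("step_generation: population bookkeeping mismatch (internal error)")
  }
  list(
    chromosomes = out,
    lineage = c(rep("recombined", counts$n_children),
                rep("mutated", counts$n_mutate),
                rep("fresh", counts$n_fresh))
  )
}

#' Detect a fitness plateau
#'
#' `TRUE` once the relative improvement of the best-so-far BIC over the last
#' `window` generations falls below `tol`. Traces shorter than `window`
#' never plateau.
#'
#' @param best_bic_trace Best-so-far BIC per generation.
#' @param window Number of trailing generations examined.
#' @param tol Relative-improvement tolerance.
#' @return Logical.
#' @export
detect_plateau <- function(best_bic_trace, window = 10, tol = 0.001) {
  n <- length(best_bic_trace)
  if (n < window) return(FALSE)
  ref <- best_bic_trace[n - window + 1]
  improvement <- (ref - best_bic_trace[n]) / max(abs(ref), 1e-12)
  improvement < tol
}

#' Elbow of the fitness-versus-feature-count curve
#'
#' Takes the best (minimum) BIC at each distinct selected-feature count and
#' finds the point of maximum perpendicular distance to the chord of the
#' curve on normalized axes.
#'
#' @param records Evaluated `fitness_record`s (>= 3 distinct feature
#'   counts; otherwise the maximum count is returned with a warning).
#' @return List: `feature_count` at the elbow, the `curve` tibble, and a
#'   `degenerate` flag (curve collinear with its chord).
#' @export
fitness_elbow <- function(records) {
  ps <- vapply(records, function(r) r$p, numeric(1))
  bs <- vapply(records, function(r) r$bic, numeric(1))
  curve <- dplyr::arrange(
    dplyr::summarise(dplyr::group_by(tibble::tibble(p = ps, bic = bs), p),
                     best_bic = min(bic), .groups = "drop"),
    p
  )
  if (nrow(curve) < 3) {
    warning("fitness_elbow: fewer than 3 distinct feature counts; returning the maximum")
    return(list(feature_count = max(curve$p), curve = curve, degenerate = TRUE))
  }
  idx <- elbow_point(curve$p, curve$best_bic)
  degenerate <- idx %in% c(1L, nrow(curve))
  if (degenerate) {
    warning("fitness_elbow: curve is degenerate (elbow at an endpoint)")
  }
  list(feature_count = curve$p[idx], curve = curve, degenerate = degenerate)
}

# Aggregate permutation importance over the best donor models: each donor is
# refit on the full training partition and its features scored by mean AUC
# drop; features outside a donor's subset contribute 0 for that donor.
aggregate_importances <- function(records, spec, x, y, n_donors, repeats,
                                  cv_cap, seed) {
  ord <- order(vapply(records, function(r) r$bic, numeric(1)))
  donors <- records[ord][seq_len(min(n_donors, length(records)))]
  p_all <- ncol(x)
  total <- stats::setNames(rep(0, p_all), colnames(x))
  for (i in seq_along(donors)) {
    chr <- donors[[i]]$chromosome
    xs <- x[, chr$subset, drop = FALSE]
    est <- make_estimator(spec, chr$hyperparams)
    est <- fit_estimator(est, xs, y, seed = substream_seed(seed, paste0("imp", i)))
    imp <- permutation_importance(
      function(newx) predict_proba(est, newx), xs, y,
      n_repeats = repeats, seed = substream_seed(seed, paste0("pimp", i))
    )
    total[colnames(xs)] <- total[colnames(xs)] + imp$importance
  }
  total / length(donors)
}

#' Run the integrated evolutionary learner
#'
#' The full loop: initialize a random population of (hyperparameters,
#' feature subset) chromosomes; evaluate each by stratified cross-validation
#' against the BIC fitness; breed generations (recombine / mutate / discard /
#' refresh) until the fitness plateaus; then, optionally, warm-restart with
#' the feature pool constrained to high-importance features at the
#' fitness-elbow threshold and escalate the cutoff by 2-10 SDs of the
#' importance distribution, each phase a reduced-population mini-run.
#'
#' @param x Numeric predictor matrix (prepared training partition).
#' @param y Binary 0/1 labels.
#' @param family Classifier family (see [estimator_spec()]).
#' @param config An [evolution_config()].
#' @param space Optional `search_space` override.
#' @param spec Optional full [estimator_spec()] override (takes precedence).
#' @param seed Master seed; the whole run is reproducible from it.
#' @param n_best Number of top models retained in the result (default 100).
#' @return An `iel_result`: ranked `best` records, the full `records` list,
#'   a `generation_log` tibble, aggregated `importances`, the `elbow`, fit
#'   counts and the configuration. Has [tidy()], [glance()] and
#'   `autoplot()` methods.
#' @export
run_iel <- function(x, y, family = "logistic_elasticnet",
                    config = evolution_config(), space = NULL, spec = NULL,
                    seed = 1L, n_best = 100) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- sprintf("f%03d", seq_len(ncol(x)))
  y <- as.integer(y)
  stopifnot(nrow(x) == length(y), all(y %in% c(0L, 1L)))
  if (is.null(spec)) spec <- estimator_spec(family, space = space)
  family <- spec$family
  cv_plan_seed <- substream_seed(seed, "cvplan")

  evaluate <- function(chroms, phase, gen) {
    lapply(seq_along(chroms), function(i) {
      rec <- cv_fit(spec, chroms[[i]]$hyperparams, x, y, chroms[[i]]$subset,
                    seed = substream_seed(seed, paste0(phase, gen, "e", i)),
                    cap = config$cv_cap, plan_seed = cv_plan_seed)
      rec$phase <- phase
      rec$generation <- gen
      rec
    })
  }

  run_phase <- function(pool, counts, max_gens, phase, phase_seed) {
    chroms <- init_population(spec$space, config, pool, seed = phase_seed,
                              n = counts$population)
    lineage <- rep("fresh", counts$population)
    all_recs <- list()
    trace <- numeric(0)
    logs <- list()
    gen <- 0L
    repeat {
      gen <- gen + 1L
      recs <- evaluate(chroms, phase, gen)
      for (i in seq_along(recs)) recs[[i]]$lineage <- lineage[i]
      all_recs <- c(all_recs, recs)
      bics <- vapply(recs, function(r) r$bic, numeric(1))
      gen_best <- min(bics)
      best_so_far <- if (length(trace)) min(trace[length(trace)], gen_best) else gen_best
      trace <- c(trace, best_so_far)
      logs[[gen]] <- tibble::tibble(
        phase = phase, generation = gen, n_models = length(recs),
        n_recombined = sum(lineage == "recombined"),
        n_mutated = sum(lineage == "mutated"),
        n_fresh = sum(lineage == "fresh"),
        best_bic = gen_best, best_so_far = best_so_far
      )
      if (gen >= max_gens ||
          detect_plateau(trace, config$plateau_window, config$plateau_tol)) {
        break
      }
      nxt <- step_generation(recs, config, spec$space, pool,
                             seed = substream_seed(phase_seed, paste0("g", gen)),
                             counts = counts)
      chroms <- nxt$chromosomes
      lineage <- nxt$lineage
    }
    list(records = all_recs, trace = trace, log = dplyr::bind_rows(logs))
  }

  pool <- seq_len(ncol(x))
  main <- run_phase(pool, config$counts, config$max_generations, "main",
                    substream_seed(seed, "main"))
  all_records <- main$records
  logs <- list(main$log)
  importances <- NULL
  elbow <- NULL

  run_phase_quiet <- function(pool_m, nm) {
    withCallingHandlers(
      run_phase(pool_m, config$warm_counts, config$warm_max_generations,
                nm, substream_seed(seed, nm)),
      warning = function(w) {
        if (grepl("smaller than max subset", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    )
  }

  if (config$warm_start) {
    # recursive learning: re-aggregate importances, re-derive the fitness
    # elbow and re-constrain the pool until it stops shrinking
    pool_prev <- length(pool)
    round <- 0L
    repeat {
      importances <- aggregate_importances(
        all_records, spec, x, y, config$importance_donors,
        config$importance_repeats, config$cv_cap,
        substream_seed(seed, paste0("importance", round))
      )
      elbow <- fitness_elbow(all_records)
      ranked_imp <- sort(importances, decreasing = TRUE)
      # The fitness elbow is only as good as the fitness-vs-count curve; on
      # short runs that curve is unconverged and the count overshoots. The
      # scree elbow of the importance profile bounds the pool to features
      # with appreciable measured importance.
      k_scree <- elbow_point(seq_along(ranked_imp), unname(ranked_imp))
      thr_idx <- max(2, min(elbow$feature_count, k_scree, length(ranked_imp)))
      elbow$scree_count <- k_scree
      elbow$importance_threshold <- ranked_imp[[thr_idx]]
      pool_new <- which(importances >= elbow$importance_threshold)
      if (length(pool_new) < 2) {
        pool_new <- order(importances, decreasing = TRUE)[1:2]
      }
      if (round > 0L && length(pool_new) >= pool_prev) break
      ph <- run_phase_quiet(pool_new, paste0("warm", round))
      all_records <- c(all_records, ph$records)
      logs[[length(logs) + 1]] <- ph$log
      pool_prev <- length(pool_new)
      round <- round + 1L
      if (round >= config$warm_recursions) break
    }
    # escalate the importance cutoff: mean + m * SD phases
    for (m in config$sd_multipliers) {
      cutoff <- mean(importances) + m * stats::sd(importances)
      pool_m <- which(importances >= cutoff)
      if (length(pool_m) < max(2, config$subset_range[1])) break
      ph <- run_phase_quiet(pool_m, paste0("warm_sd", m))
      all_records <- c(all_records, ph$records)
      logs[[length(logs) + 1]] <- ph$log
    }
  }

  ord <- order(vapply(all_records, function(r) r$bic, numeric(1)))
  best <- all_records[ord][seq_len(min(n_best, length(all_records)))]
  structure(
    list(
      best = best, records = all_records,
      generation_log = dplyr::bind_rows(logs),
      importances = importances, elbow = elbow,
      config = config, family = family, spec = spec, seed = seed,
      cv_plan_seed = cv_plan_seed, n_fits = length(all_records)
    ),
    class = "iel_result"
  )
}

#' @export
print.iel_result <- function(x, ...) {
  cat(sprintf("<iel_result> family=%s, %d model fits, best BIC=%.3f (p=%d)\n",
              x$family, x$n_fits, x$best[[1]]$bic, x$best[[1]]$p))
  invisible(x)
}

#' Tidy the ranked best models of an IEL run
#'
#' @param x An `iel_result`.
#' @param ... Unused.
#' @return A tibble with one row per retained model: rank, phase,
#'   generation, BIC, log-likelihood, feature count, hyperparameter columns
#'   and the selected feature subset as a list column.
#' @importFrom generics tidy
#' @method tidy iel_result
#' @export
tidy.iel_result <- function(x, ...) {
  hp <- dplyr::bind_rows(lapply(x$best, function(r) {
    tibble::as_tibble(r$chromosome$hyperparams)
  }))
  dplyr::bind_cols(
    tibble::tibble(
      rank = seq_along(x$best),
      phase = vapply(x$best, function(r) r$phase, character(1)),
      generation = vapply(x$best, function(r) r$generation, numeric(1)),
      bic = vapply(x$best, function(r) r$bic, numeric(1)),
      loglik = vapply(x$best, function(r) r$loglik, numeric(1)),
      n_features = vapply(x$best, function(r) r$p, numeric(1))
    ),
    hp,
    tibble::tibble(subset = lapply(x$best, function(r) r$chromosome$subset))
  )
}

#' One-row summary of an IEL run
#' @param x An `iel_result`.
#' @param ... Unused.
#' @importFrom generics glance
#' @method glance iel_result
#' @export
glance.iel_result <- function(x, ...) {
  tibble::tibble(
    family = x$family,
    n_fits = x$n_fits,
    n_generations = nrow(x$generation_log),
    best_bic = x$best[[1]]$bic,
    best_n_features = x$best[[1]]$p,
    elbow_feature_count = if (is.null(x$elbow)) NA_real_ else x$elbow$feature_count
  )
}

#' Fitness trace of an IEL run
#'
#' Best-so-far BIC against the cumulative generation index, one line per
#' optimization phase.
#'
#' @param object An `iel_result`.
#' @param ... Unused.
#' @importFrom ggplot2 autoplot
#' @method autoplot iel_result
#' @export
autoplot.iel_result <- function(object, ...) {
  log <- dplyr::mutate(object$generation_log,
                       step = dplyr::row_number())
  ggplot2::ggplot(log, ggplot2::aes(x = .data$step, y = .data$best_so_far,
                                    colour = .data$phase)) +
    ggplot2::geom_step(linewidth = 0.6) +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "generation (cumulative)", y = "best-so-far BIC",
                  colour = "phase") +
    ggplot2::theme_minimal()
}
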