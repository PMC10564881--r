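toy_space <- search_space(
  space_real("a", 0, 1),
  space_real("b", 1e-3, 1e3, log = TRUE),
  space_integer("c", 1, 9)
)

sample_hyperparams_test <- function(space, seed) {
  set.seed(seed)
  list(a = runif(1), b = exp(runif(1, log(1e-3), log(1e3))),
       c = sample(1:9, 1))
}

test_that("population initialization respects counts, bounds and the seed", {
  cfg <- evolution_config(population = 100)
  pop <- init_population(toy_space, cfg, pool = 1:160, seed = 1)
  expect_length(pop, 100)
  sizes <- lengths(lapply(pop, `[[`, "subset"))
  expect_true(all(sizes >= 2 & sizes <= 50))
  expect_true(all(unlist(lapply(pop, `[[`, "subset")) %in% 1:160))
  expect_true(all(!vapply(pop, function(c) anyDuplicated(c$subset) > 0,
                          logical(1))))
  pop2 <- init_population(toy_space, cfg, pool = 1:160, seed = 1)
  expect_identical(pop, pop2)
  # small pools shrink the subset bound with a warning
  expect_warning(init_population(toy_space, cfg, pool = 1:10, seed = 1),
                 "shrinking")
})

test_that("generation bookkeeping reproduces the reference proportions", {
  c100 <- generation_counts(100)
  expect_equal(c100[c("n_best", "n_parents", "n_children", "n_mutate",
                      "n_discard", "n_fresh", "n_donors")],
               list(n_best = 80, n_parents = 40, n_children = 20,
                    n_mutate = 20, n_discard = 20, n_fresh = 60,
                    n_donors = 60))
  w50 <- generation_counts(50, warm = TRUE)
  expect_equal(w50$n_children, 20)
  expect_equal(w50$n_mutate, 10)
  expect_equal(w50$n_fresh, 20)
})

test_that("recombination copies before the pivot and averages after", {
  a <- list(hyperparams = list(a = 0.2, b = 1, c = 3L), subset = c(1, 2))
  b <- list(hyperparams = list(a = 0.8, b = 100, c = 7L), subset = c(3, 4))
  child <- recombine(a, b, toy_space, seed = 1)
  # pivot at floor(3/2) = 1: gene 1 copied from parent a
  expect_equal(child$hyperparams$a, 0.2)
  # log-scaled gene: geometric mean
  expect_equal(child$hyperparams$b, 10)
  expect_equal(child$hyperparams$c, 5L)
  # identical parents: fixed point
  same <- recombine(a, a, toy_space, seed = 2)
  expect_equal(same$hyperparams, a$hyperparams)
  # one-gene space: pivot 0, child is the parent mean
  one <- search_space(space_real("a", 0, 1))
  ch1 <- recombine(list(hyperparams = list(a = 0.2), subset = 1),
                   list(hyperparams = list(a = 0.6), subset = 2),
                   one, seed = 3)
  expect_equal(ch1$hyperparams$a, 0.4)
  # averaging keeps every gene inside its bounds
  for (s in 1:20) {
    pa <- list(hyperparams = sample_hyperparams_test(toy_space, s),
               subset = c(1, 2))
    pb <- list(hyperparams = sample_hyperparams_test(toy_space, s + 100),
               subset = c(3, 4))
    ch <- recombine(pa, pb, toy_space, seed = s)
    expect_true(ch$hyperparams$a >= 0 && ch$hyperparams$a <= 1)
    expect_true(ch$hyperparams$b >= 1e-3 && ch$hyperparams$b <= 1e3)
    expect_true(ch$hyperparams$c >= 1 && ch$hyperparams$c <= 9)
  }
})

test_that("mutation shifts one gene, reflecting at the bounds", {
  interior <- list(hyperparams = list(a = 0.5, b = 1, c = 5L),
                   subset = c(1, 2))
  for (s in 1:30) {
    m <- mutate_chromosome(interior, toy_space, seed = s)
    expect_identical(m$subset, interior$subset)
    # exactly one gene changed
    changed <- sum(!mapply(identical, m$hyperparams, interior$hyperparams))
    expect_equal(changed, 1)
    # deterministic for a fixed seed
    expect_identical(m, mutate_chromosome(interior, toy_space, seed = s))
  }
  # shifts past a bound reflect back inside
  boundary <- list(hyperparams = list(a = 0.99, b = 990, c = 9L),
                   subset = c(1, 2))
  for (s in 1:30) {
    m <- mutate_chromosome(boundary, toy_space, seed = s)
    expect_true(m$hyperparams$a >= 0 && m$hyperparams$a <= 1)
    expect_true(m$hyperparams$b >= 1e-3 - 1e-12 &&
                  m$hyperparams$b <= 1e3 + 1e-9)
    expect_true(m$hyperparams$c >= 1 && m$hyperparams$c <= 9)
  }
})

test_that("donor feature sets are allocated in rank order", {
  donors <- lapply(1:60, function(i) fake_record(bic = i, subset = c(i, i + 1)))
  children <- lapply(1:40, function(i) list(hyperparams = list(a = 0),
                                            subset = c(99, 100)))
  out <- allocate_feature_sets(donors, children)
  expect_equal(out[[1]]$subset, c(1, 2))
  expect_equal(out[[40]]$subset, c(40, 41))
  # 1 donor, 1 child
  one <- allocate_feature_sets(donors[1], children[1])
  expect_equal(one[[1]]$subset, c(1, 2))
  # fewer donors than children: recycled from the top, with a warning
  expect_warning(rec <- allocate_feature_sets(donors[1:2], children[1:4]),
                 "recycling")
  expect_equal(rec[[3]]$subset, c(1, 2))
})

test_that("step_generation partitions the population exactly as configured", {
  cfg <- evolution_config(population = 100)
  recs <- lapply(1:100, function(i) {
    fake_record(bic = 1000 - i, subset = sort(sample(1:160, 5)),
                hyperparams = list(a = runif(1), b = 1, c = 3L))
  })
  nxt <- step_generation(recs, cfg, toy_space, pool = 1:160, seed = 1)
  expect_length(nxt$chromosomes, 100)
  expect_equal(as.numeric(table(nxt$lineage)[c("recombined", "mutated", "fresh")]),
               c(20, 20, 60))
  # ranking invariance: permuting record order leaves the bred set unchanged
  perm <- sample(100)
  nxt2 <- step_generation(recs[perm], cfg, toy_space, pool = 1:160, seed = 1)
  expect_identical(nxt$chromosomes, nxt2$chromosomes)
  # bookkeeping mismatch is a hard error
  expect_error(step_generation(recs[1:50], cfg, toy_space, 1:160, 1))
})

test_that("plateau detection follows the relative-improvement rule", {
  expect_false(detect_plateau(seq(1000, 100, by = -100), window = 5,
                              tol = 0.001))
  expect_true(detect_plateau(rep(500, 10), window = 10, tol = 0.001))
  # improving 0.01% per generation with tol 0.1% over window 5: plateaued
  tr <- 1000 * (1 - 0.0001)^(0:20)
  expect_true(detect_plateau(tr, window = 5, tol = 0.001))
  expect_false(detect_plateau(c(500), window = 5, tol = 0.001))
})

test_that("the fitness elbow finds the corner of an L-shaped curve", {
  # corner at p = 6
  ps <- c(2, 4, 6, 10, 20, 30, 40)
  bic <- c(600, 400, 200, 195, 190, 188, 186)
  recs <- mapply(function(p, b) fake_record(b, seq_len(p)), ps, bic,
                 SIMPLIFY = FALSE)
  el <- fitness_elbow(recs)
  expect_equal(el$feature_count, 6)
  expect_false(el$degenerate)
  # elbow invariant to axis rescaling
  recs2 <- mapply(function(p, b) fake_record(b * 1000, seq_len(p)), ps, bic,
                  SIMPLIFY = FALSE)
  expect_equal(fitness_elbow(recs2)$feature_count, 6)
  # perfectly linear curve: endpoint, flagged degenerate
  lin <- mapply(function(p, b) fake_record(b, seq_len(p)),
                c(2, 4, 6, 8), c(100, 200, 300, 400), SIMPLIFY = FALSE)
  expect_warning(eld <- fitness_elbow(lin), "degenerate")
  expect_true(eld$degenerate)
  # fewer than 3 distinct counts: maximum with a warning
  expect_warning(e2 <- fitness_elbow(lin[c(1, 2)]), "fewer than 3")
  expect_equal(e2$feature_count, 4)
})

test_that("a small IEL run is reproducible and keeps its invariants", {
  set.seed(7)
  x <- matrix(rnorm(150 * 12), 150, 12)
  y <- rbinom(150, 1, plogis(1.5 * x[, 3] - x[, 9]))
  cfg <- evolution_config(population = 10, max_generations = 5,
                          warm_start = FALSE, plateau_window = 10)
  r1 <- suppressWarnings(run_iel(x, y, "logistic_elasticnet", cfg, seed = 5))
  r2 <- suppressWarnings(run_iel(x, y, "logistic_elasticnet", cfg, seed = 5))
  expect_identical(r1$best[[1]]$bic, r2$best[[1]]$bic)
  expect_identical(r1$generation_log, r2$generation_log)
  # best-so-far is non-increasing; population size constant
  expect_true(all(diff(r1$generation_log$best_so_far) <= 0))
  expect_true(all(r1$generation_log$n_models == 10))
  expect_equal(r1$n_fits, 5 * 10)
  # subset bounds never violated after any operator
  sizes <- vapply(r1$records, function(r) r$p, numeric(1))
  expect_true(all(sizes >= 2 & sizes <= 12))
})

test_that("tidy, glance and autoplot summarize a run", {
  set.seed(8)
  x <- matrix(rnorm(120 * 8), 120, 8)
  y <- rbinom(120, 1, plogis(x[, 1]))
  cfg <- evolution_config(population = 10, max_generations = 3,
                          warm_start = FALSE)
  res <- suppressWarnings(run_iel(x, y, "logistic_elasticnet", cfg, seed = 2,
                                  n_best = 5))
  td <- generics::tidy(res)
  expect_equal(nrow(td), 5)
  expect_true(all(c("rank", "bic", "mixing", "strength", "subset") %in%
                    names(td)))
  expect_true(!is.unsorted(td$bic))
  gl <- generics::glance(res)
  expect_equal(gl$n_fits, 30)
  pl <- ggplot2::autoplot(res)
  expect_s3_class(pl, "ggplot")
})
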