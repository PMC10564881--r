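# Shared fixtures, all generated in code.

# The parameter-recovery cohort: 400 subjects, 40 mixed predictors over a
# rank-4 latent with heavy feature noise, four linear planted effects of
# size 1.3 (generator-recorded Bayes AUC ~0.90), 30% cases, complete data.
recovery_cohort <- function(seed) {
  inf <- data.frame(feature = c(3, 10, 20, 30), type = "linear", size = 1.3)
  spec <- cohort_spec(
    n_subjects = 400, n_features = 40,
    informative = list(dep = inf), case_rate = c(dep = 0.3),
    missing_rate = 0, latent_rank = 4, noise_sd = 3, seed = seed
  )
  generate_cohort(spec)
}

recovery_planted <- c("f003", "f010", "f020", "f030")

# Two well-separated planted connectivity states over 5 components.
planted_states <- function() {
  s1 <- diag(5)
  s2 <- matrix(0.7, 5, 5); diag(s2) <- 1
  list(s1, s2)
}

# Brute-force AUC oracle: Mann-Whitney concordance with half credit for
# ties, enumerated over all positive-negative pairs.
concordance_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Exhaustive Shapley oracle over all 2^p coalitions, with coalition value
# v(S) = mean over background rows of f(x with S from the explained row).
exhaustive_shapley <- function(f, xb, xrow) {
  p <- length(xrow)
  v <- function(S) {
    m <- xb
    for (j in S) m[, j] <- xrow[j]
    mean(f(m))
  }
  phi <- numeric(p)
  subsets <- lapply(0:(2^p - 1), function(b) which(bitwAnd(b, 2^(0:(p - 1))) > 0))
  for (j in seq_len(p)) {
    for (S in subsets) {
      if (j %in% S) next
      w <- factorial(length(S)) * factorial(p - length(S) - 1) / factorial(p)
      phi[j] <- phi[j] + w * (v(c(S, j)) - v(S))
    }
  }
  phi
}

# Fabricate a minimal fitness record for operator-level tests that do not
# need a real cross-validated fit.
fake_record <- function(bic, subset, p = length(subset), hyperparams = list(a = 1)) {
  structure(
    list(chromosome = list(hyperparams = hyperparams, subset = subset),
         n = 100, p = p, loglik = (p * log(100) - bic) / 2, bic = bic,
         fold_metrics = NULL, importances = NULL),
    class = "fitness_record"
  )
}
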