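# Internal helpers shared across modules.

# Derive a named substream seed from a master seed. All randomness in the
# package flows from a single master integer; substreams are obtained by
# hashing the stream name so that adding a new consumer never perturbs an
# existing one. Result stays below 2^31.
substream_seed <- function(master, name) {
  stopifnot(is.numeric(master), length(master) == 1)
  h <- sum(utf8ToInt(as.character(name)) * seq_along(utf8ToInt(as.character(name))))
  as.integer((as.numeric(master) * 2654435L + h * 97L) %% 2147483647)
}

# Run an expression under a local RNG state so package internals never
# disturb the caller's .Random.seed.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

#' Area under the ROC curve by trapezoidal integration
#'
#' Computes the ROC curve and its area for a vector of scores against binary
#' labels. The trapezoidal area equals the Mann-Whitney concordance
#' probability: the chance a random positive outscores a random negative,
#' with half credit for ties.
#'
#' @param scores Numeric vector of classifier scores (larger = more positive).
#' @param labels Binary labels (0/1 or logical), same length as `scores`.
#' @return A list with `auc` (scalar) and `curve`, a tibble of
#'   (`fpr`, `tpr`, `threshold`) points from (0,0) to (1,1).
#' @examples
#' roc_auc(c(.9, .8, .1, .2), c(1, 1, 0, 0))$auc
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("roc_auc: both classes must be present in `labels`")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  # collapse ties: one ROC vertex per distinct score
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y)
  fp <- cumsum(1L - y)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / n_pos)
  fpr <- c(0, fp[last] / n_neg)
  thr <- c(Inf, s[last])
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(
    auc = auc,
    curve = tibble::tibble(fpr = fpr, tpr = tpr, threshold = thr)
  )
}

# sample() without the scalar-x surprise: always samples from the elements
# of x, even when length(x) == 1.
resample <- function(x, size = length(x), replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

# log-likelihood of binary outcomes under predicted class-1 probabilities,
# with a probability floor to avoid -Inf.
binomial_loglik <- function(prob1, y, floor = 1e-12) {
  p <- ifelse(y == 1, prob1, 1 - prob1)
  sum(log(pmax(p, floor)))
}

#' Bayes Information Criterion used as the evolutionary fitness
#'
#' `bic = p * log(n) - 2 * loglik`, where `p` is the number of selected
#' features (the complexity actually searched over), `n` the sample count and
#' `loglik` the summed out-of-fold binomial log-likelihood in nats. Lower is
#' better.
#'
#' @param loglik Summed validation log-likelihood (nats).
#' @param n Number of scored observations.
#' @param p Number of selected features (>= 1).
#' @return The BIC value.
#' @export
bic_fitness <- function(loglik, n, p) {
  stopifnot(p >= 1, n >= 1)
  p * log(n) - 2 * loglik
}
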