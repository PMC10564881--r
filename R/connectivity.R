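z_cap <- atanh(0.999999)

# Upper-triangle (row-major) vectorization shared by all connectivity code.
upper_tri_vec <- function(m) m[upper.tri(m)]

#' Static Fisher-z connectivity per subject
#'
#' Pearson correlation between every unordered pair of component
#' timecourses, Fisher-transformed (z = atanh(k)) to stabilize variance.
#' Correlations with |k| -> 1 (e.g. duplicated components) are capped at
#' atanh(0.999999) with a warning; constant components are an error.
#'
#' @param tc A `timecourse_set` (or list of components x timepoints
#'   matrices).
#' @return A tibble with one row per subject and one `z_<i>_<j>` column per
#'   component pair (upper triangle order).
#' @export
static_connectivity <- function(tc) {
  mats <- if (inherits(tc, "timecourse_set")) tc$subjects else tc
  c_comp <- nrow(mats[[1]])
  stopifnot(ncol(mats[[1]]) >= 3)
  pairs <- which(upper.tri(diag(c_comp)), arr.ind = TRUE)
  pair_names <- sprintf("z_%d_%d", pairs[, "row"], pairs[, "col"])
  capped <- FALSE
  rows <- lapply(seq_along(mats), function(s) {
    m <- mats[[s]]
    sds <- apply(m, 1, stats::sd)
    if (any(sds == 0)) {
      stop(sprintf("static_connectivity: constant component(s) %s in subject %d",
                   paste(which(sds == 0), collapse = ","), s))
    }
    k <- stats::cor(t(m))
    kv <- upper_tri_vec(k)
    if (any(abs(kv) >= 0.999999)) capped <<- TRUE
    kv <- pmin(pmax(kv, -0.999999), 0.999999)
    atanh(kv)
  })
  if (capped) {
    warning("static_connectivity: |correlation| ~ 1 capped at atanh(0.999999)")
  }
  out <- tibble::as_tibble(as.data.frame(do.call(rbind, rows)))
  names(out) <- pair_names
  dplyr::bind_cols(tibble::tibble(subject = seq_along(mats)), out)
}

#' Sliding-window correlation matrices
#'
#' Rectangular windows of `window` timepoints advanced by `step`, yielding
#' `floor((T - window) / step) + 1` windows; each window's matrix is the
#' Pearson correlation of the components over that span (symmetric, unit
#' diagonal).
#'
#' @param x A components x timepoints matrix (one subject).
#' @param window Window length in timepoints (>= 2).
#' @param step Step in timepoints (default 1).
#' @return List of correlation matrices.
#' @export
sliding_windows <- function(x, window, step = 1) {
  t_len <- ncol(x)
  stopifnot(window >= 2, step >= 1)
  if (window > t_len) {
    stop("sliding_windows: window longer than the timecourse")
  }
  starts <- seq(1, t_len - window + 1, by = step)
  lapply(starts, function(s) {
    k <- stats::cor(t(x[, s:(s + window - 1), drop = FALSE]))
    k[is.na(k)] <- 0
    diag(k) <- 1
    k
  })
}

#' Cluster connectivity windows into brain states
#'
#' Vectorizes every window (upper triangle) across all subjects and runs
#' seeded k-means with multiple restarts; the returned solution has the
#' lowest within-cluster inertia among restarts.
#'
#' @param windows_by_subject List (per subject) of lists of window
#'   correlation matrices, as from [sliding_windows()].
#' @param k Number of states (>= 1, <= total windows).
#' @param seed Integer seed.
#' @param nstart Number of k-means restarts.
#' @return A list: `centroids` (k x pairs matrix), `labels` (per-subject
#'   integer state sequences in 1..k), `inertia`.
#' @export
cluster_states <- function(windows_by_subject, k, seed = 1L, nstart = 10) {
  vecs <- lapply(windows_by_subject, function(ws) {
    do.call(rbind, lapply(ws, upper_tri_vec))
  })
  all_w <- do.call(rbind, vecs)
  stopifnot(k >= 1)
  if (k > nrow(all_w)) stop("cluster_states: k exceeds the number of windows")
  km <- with_seed(substream_seed(seed, "kmeans"), {
    stats::kmeans(all_w, centers = k, nstart = nstart, iter.max = 100)
  })
  counts <- vapply(vecs, nrow, integer(1))
  ends <- cumsum(counts)
  starts <- c(1, utils::head(ends, -1) + 1)
  labels <- lapply(seq_along(vecs), function(i) km$cluster[starts[i]:ends[i]])
  list(centroids = km$centers, labels = labels, inertia = km$tot.withinss)
}

#' Select the number of brain states by the inertia elbow
#'
#' Runs seeded k-means over `k_range` and returns the k at the point of
#' maximum perpendicular distance to the chord of the (k, inertia) curve on
#' normalized axes.
#'
#' @inheritParams cluster_states
#' @param k_range Candidate state counts (default 2:8).
#' @return The selected k.
#' @export
select_n_states <- function(windows_by_subject, k_range = 2:8, seed = 1L) {
  inert <- vapply(k_range, function(k) {
    cluster_states(windows_by_subject, k, seed = seed, nstart = 5)$inertia
  }, numeric(1))
  k_range[elbow_point(k_range, inert)]
}

#' Dynamic connectivity fluidity metrics from a state sequence
#'
#' Summarizes a subject's trajectory among brain states: the number of
#' distinct states traversed, the number of switches (consecutive unequal
#' labels), the total distance traveled (sum of L1 distances between the
#' centroids of consecutive switched states) and the maximal L1 span (the
#' largest pairwise L1 distance among the visited centroids).
#'
#' @param labels Integer state sequence (non-empty).
#' @param centroids Matrix with one row per state (vectorized centroid).
#' @return One-row tibble: `n_states_traversed`, `n_switches`,
#'   `max_l1_span`, `total_l1_distance`.
#' @export
dynamic_metrics <- function(labels, centroids) {
  stopifnot(length(labels) >= 1, all(labels >= 1), all(labels <= nrow(centroids)))
  visited <- sort(unique(labels))
  switches <- which(diff(labels) != 0)
  total <- 0
  for (i in switches) {
    total <- total + sum(abs(centroids[labels[i], ] - centroids[labels[i + 1], ]))
  }
  span <- 0
  if (length(visited) > 1) {
    for (a in seq_along(visited)) {
      for (b in seq_len(a - 1)) {
        d <- sum(abs(centroids[visited[a], ] - centroids[visited[b], ]))
        span <- max(span, d)
      }
    }
  }
  tibble::tibble(
    n_states_traversed = length(visited),
    n_switches = length(switches),
    max_l1_span = span,
    total_l1_distance = total
  )
}

#' Residualize features on nuisance covariates with the general linear model
#'
#' Ordinary-least-squares residuals of every feature column on the covariate
#' matrix (an intercept is added); residuals are orthogonal to the
#' covariates.
#'
#' @param features Numeric matrix (subjects x features).
#' @param covariates Numeric matrix (subjects x covariates), full column
#'   rank after adding an intercept.
#' @return The residual feature matrix.
#' @export
residualize <- function(features, covariates) {
  features <- as.matrix(features)
  x <- cbind(intercept = 1, as.matrix(covariates))
  qrx <- qr(x)
  if (qrx$rank < ncol(x)) {
    bad <- colnames(x)[setdiff(seq_len(ncol(x)), qrx$pivot[seq_len(qrx$rank)])]
    stop("residualize: covariates are rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  qr.resid(qrx, features)
}

# Elbow of a curve: index of maximum perpendicular distance to the chord
# joining the first and last points, after normalizing both axes to [0,1].
# The signed distance selects the convex corner (the point furthest BELOW
# the chord), the usual convention for L-shaped loss/inertia curves.
elbow_point <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  nx <- (x - min(x)) / max(diff(range(x)), 1e-12)
  ny <- (y - min(y)) / max(diff(range(y)), 1e-12)
  x0 <- nx[1]; y0 <- ny[1]
  x1 <- nx[length(nx)]; y1 <- ny[length(ny)]
  len <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
  # for x increasing, positive distance = below the chord
  d <- ((y1 - y0) * nx - (x1 - x0) * ny + x1 * y0 - y1 * x0) / max(len, 1e-12)
  which.max(d)
}
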