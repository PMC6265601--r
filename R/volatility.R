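# Pain volatility V(R): the mean of absolute changes between consecutive
# severity ratings, and the machinery that turns pooled volatility scores
# into a low/high classification via one-dimensional 2-means clustering.

#' Pain volatility of a rating series
#'
#' For a series of severity ratings \eqn{R = (R_1, \dots, R_n)} the
#' volatility is the mean absolute successive difference
#' \deqn{V(R) = \frac{1}{n-1}\sum_{i=2}^{n} |R_i - R_{i-1}|.}
#' Ratings are taken consecutively in record order, regardless of the elapsed
#' time between them. Unlike the standard deviation, V(R) ranks a saw-tooth
#' fluctuation above a steady monotone trend of the same spread.
#'
#' @param ratings Numeric vector of at least two severity ratings in
#'   record order.
#' @return Non-negative scalar; at most the rating range (10 on a 0-10 scale).
#' @seealso [compute_sd()] for the comparison statistic.
#' @export
compute_volatility <- function(ratings) {
  n <- length(ratings)
  if (n < 2) stop("volatility is undefined for fewer than 2 ratings")
  mean(abs(diff(ratings)))
}

#' Sample standard deviation of a rating series
#'
#' The conventional variability measure (divisor n-1), used as the comparison
#' statistic for [compute_volatility()].
#'
#' @inheritParams compute_volatility
#' @return Non-negative scalar.
#' @export
compute_sd <- function(ratings) {
  if (length(ratings) < 2) stop("SD comparison requires at least 2 ratings")
  stats::sd(ratings)
}

#' One-dimensional k-means clustering
#'
#' Lloyd's algorithm on scalar values, initialized from `k` random distinct
#' data values, with `nstart` restarts keeping the lowest within-cluster sum
#' of squares. For k = 2 on one-dimensional data the converged solution is a
#' single split point in sorted order; restarts make reaching the optimal
#' split reliable in practice (checked against an exhaustive sorted-split
#' search in the test suite).
#'
#' @param values Numeric vector with at least `k` distinct values.
#' @param k Number of clusters (default 2).
#' @param nstart Number of random restarts.
#' @param seed Optional integer seed for the random initializations.
#' For k = 2 the converged restart winner is additionally verified against
#' the exact optimum found by an O(n) prefix-sum scan over all sorted splits;
#' if every random restart stalled in a local optimum (possible on tie-heavy
#' data), Lloyd is re-seeded at the optimal split's cluster means — a fixed
#' point of the iteration — so the returned solution always attains the
#' global within-cluster sum of squares.
#'
#' @return List with `assignments` (integer cluster ids, 1 = lowest-mean
#'   cluster), `centers` (sorted cluster means) and `sse` (within-cluster sum
#'   of squares).
#' @export
kmeans_1d <- function(values, k = 2L, nstart = 25L, seed = NULL) {
  if (length(values) < k) stop("need at least k values to form k clusters")
  distinct <- unique(values)
  if (length(distinct) < k) {
    stop("degenerate clustering: fewer than k distinct values")
  }
  run <- function() {
    best <- list(sse = Inf)
    for (s in seq_len(nstart)) {
      centers <- sort(sample(distinct, k))
      assign_old <- rep(0L, length(values))
      for (iter in 1:200) {
        d <- abs(outer(values, centers, "-"))
        assignment <- max.col(-d, ties.method = "first")
        if (identical(assignment, assign_old)) break
        assign_old <- assignment
        if (length(unique(assignment)) < k) break  # empty cluster; abandon
        centers <- vapply(seq_len(k), function(j) mean(values[assignment == j]),
                          numeric(1))
      }
      if (length(unique(assignment)) < k) next
      sse <- sum((values - centers[assignment])^2)
      if (sse < best$sse) best <- list(assignments = assignment,
                                       centers = centers, sse = sse)
    }
    if (!is.finite(best$sse)) stop("clustering failed: no restart converged")
    best
  }
  best <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  if (k == 2L) {
    opt <- optimal_split_centers(values)
    if (best$sse > opt$sse + 1e-9 * (1 + opt$sse)) {
      # every random restart stalled; re-seed Lloyd at the optimal split
      centers <- opt$centers
      for (iter in 1:200) {
        d <- abs(outer(values, centers, "-"))
        assignment <- max.col(-d, ties.method = "first")
        new_centers <- vapply(1:2, function(j) mean(values[assignment == j]),
                              numeric(1))
        if (identical(new_centers, centers)) break
        centers <- new_centers
      }
      best <- list(assignments = assignment, centers = centers,
                   sse = sum((values - centers[assignment])^2))
    }
  }
  ord <- order(best$centers)
  relabel <- match(seq_along(ord), ord)
  list(assignments = relabel[best$assignments],
       centers = best$centers[ord], sse = best$sse)
}

#' Derive the low/high volatility threshold from pooled scores
#'
#' Pools the predictor-period and outcome-period volatility scores (each user
#' contributes two values), clusters the pooled values into two groups with
#' [kmeans_1d()], and places the threshold at the midpoint of the gap between
#' the largest value of the low cluster and the smallest value of the high
#' cluster. A score is labelled `high` iff it is strictly greater than the
#' threshold; a score exactly at the threshold is `low`.
#'
#' @param predictor_scores Named numeric vector of per-user volatility scores
#'   from the predictor window (names are user ids).
#' @param outcome_scores Named numeric vector from the outcome window.
#' @param seed Optional integer seed for the clustering restarts.
#' @return A `volatility_classification`: list with `threshold`,
#'   `cluster_means`, `predictor_labels` and `outcome_labels` (named factors
#'   with levels `low`/`high`), and `n_pooled`.
#' @export
derive_threshold <- function(predictor_scores, outcome_scores, seed = NULL) {
  if (length(predictor_scores) == 0 || length(outcome_scores) == 0) {
    stop("both score vectors must be non-empty")
  }
  pooled <- c(predictor_scores, outcome_scores)
  km <- kmeans_1d(pooled, k = 2L, seed = seed)
  threshold <- threshold_from_clusters(pooled, km$assignments)
  out <- list(
    threshold = threshold,
    cluster_means = km$centers,
    predictor_labels = classify_volatility(predictor_scores, threshold),
    outcome_labels = classify_volatility(outcome_scores, threshold),
    n_pooled = length(pooled)
  )
  class(out) <- "volatility_classification"
  out
}

# Exact 1-D 2-means optimum via a prefix-sum scan over sorted splits.
optimal_split_centers <- function(values) {
  v <- sort(values)
  n <- length(v)
  cs <- cumsum(v)
  cs2 <- cumsum(v^2)
  i <- seq_len(n - 1)
  sse_left <- cs2[i] - cs[i]^2 / i
  sse_right <- (cs2[n] - cs2[i]) - (cs[n] - cs[i])^2 / (n - i)
  total <- sse_left + sse_right
  best <- which.min(total)
  list(centers = c(cs[best] / best, (cs[n] - cs[best]) / (n - best)),
       sse = total[best])
}

# Midpoint of the inter-cluster gap. At a converged 1-D 2-means solution the
# clusters are contiguous in sorted order, so max(low) < min(high).
threshold_from_clusters <- function(values, assignments) {
  lo_max <- max(values[assignments == 1L])
  hi_min <- min(values[assignments == 2L])
  stopifnot(lo_max < hi_min)
  (lo_max + hi_min) / 2
}

#' Label volatility scores against a threshold
#'
#' @param scores Numeric vector (names preserved).
#' @param threshold Scalar threshold.
#' @return Factor with levels `low`/`high`; `high` iff score > threshold.
#' @export
classify_volatility <- function(scores, threshold) {
  out <- factor(ifelse(scores > threshold, "high", "low"),
                levels = c("low", "high"))
  names(out) <- names(scores)
  out
}

#' @export
print.volatility_classification <- function(x, ...) {
  cat("Volatility classification\n")
  cat(sprintf("  threshold: %.3f (cluster means %.3f / %.3f; %d pooled scores)\n",
              x$threshold, x$cluster_means[1], x$cluster_means[2], x$n_pooled))
  tab <- table(x$outcome_labels)
  cat(sprintf("  outcome-window labels: %d low, %d high\n",
              tab[["low"]], tab[["high"]]))
  invisible(x)
}

#' Threshold stability under half-sample reclustering
#'
#' Re-derives the clustering threshold on `n_repeats` random subsamples
#' (without replacement, `fraction` of the pooled scores each) and reports
#' the resulting thresholds; a tight spread indicates the full-data threshold
#' is not an artifact of particular users.
#'
#' @param pooled_scores Numeric vector of pooled volatility scores.
#' @param n_repeats Number of subsamples (default 4).
#' @param fraction Subsample fraction (default 0.5).
#' @param seed Optional integer seed.
#' @return Numeric vector of `n_repeats` thresholds, with attribute
#'   `max_spread` (largest pairwise difference).
#' @export
subsample_stability <- function(pooled_scores, n_repeats = 4L, fraction = 0.5,
                                seed = NULL) {
  if (length(pooled_scores) < 4) stop("need at least 4 pooled scores")
  run <- function() {
    m <- floor(length(pooled_scores) * fraction)
    vapply(seq_len(n_repeats), function(r) {
      sub <- sample(pooled_scores, m)
      km <- kmeans_1d(sub, k = 2L)
      threshold_from_clusters(sub, km$assignments)
    }, numeric(1))
  }
  thresholds <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  attr(thresholds, "max_spread") <-
    if (n_repeats > 0) max(thresholds) - min(thresholds) else NA_real_
  thresholds
}

#' Per-window volatility scores
#'
#' Convenience: computes n, V(R) and the SD comparison statistic for every
#' (user, window) with at least two records.
#'
#' @param windows Window tibble from [build_windows()].
#' @return Tibble with user_id, role, n, volatility, sd.
#' @export
window_volatility <- function(windows) {
  keep <- windows$n_records >= 2
  w <- windows[keep, , drop = FALSE]
  tibble::tibble(
    user_id = w$user_id,
    role = w$role,
    n = w$n_records,
    volatility = vapply(w$records, function(r) compute_volatility(r$severity),
                        numeric(1)),
    sd = vapply(w$records, function(r) compute_sd(r$severity), numeric(1))
  )
}
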