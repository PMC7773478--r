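#' Contingency table of shapelet predictions against labels
#'
#' Cross-tabulates the shapelet prediction (distance to the series at most
#' `theta`) against the binary phenotype over all series of the dataset.
#'
#' @param shapelet numeric vector, the candidate subsequence.
#' @param theta distance threshold.
#' @param dataset a [series_dataset()] containing both classes.
#' @return A list with counts `a` (label 1, predicted 1), `b` (label 0,
#'   predicted 1), `c` (label 1, predicted 0), `d` (label 0, predicted 0).
#' @export
contingency_table <- function(shapelet, theta, dataset) {
  stopifnot(inherits(dataset, "series_dataset"))
  y <- dataset$labels
  if (length(unique(y)) < 2L)
    stop("both classes must be present; the association test is undefined")
  pred <- vapply(dataset$values, function(v)
    predict_shapelet(shapelet, theta, v), integer(1))
  list(a = sum(pred == 1L & y == 1L), b = sum(pred == 1L & y == 0L),
       c = sum(pred == 0L & y == 1L), d = sum(pred == 0L & y == 0L))
}

#' Chi-squared p-value of a 2x2 table
#'
#' One-degree-of-freedom chi-squared independence test, by default without
#' Yates continuity correction (matching the discrete-test-statistic
#' framework the Tarone correction assumes). Tables with an empty
#' prediction margin (`a + b == 0` or `c + d == 0`) are degenerate -- no
#' split means no evidence -- and return p = 1.
#'
#' @param a,b,c,d non-negative counts: predicted-positive cases,
#'   predicted-positive controls, predicted-negative cases,
#'   predicted-negative controls.
#' @param correct apply the Yates continuity correction (default `FALSE`).
#' @return p-value in (0, 1].
#' @examples
#' chi2_pvalue(10, 0, 0, 10)  # ~7.7e-6
#' chi2_pvalue(5, 5, 5, 5)    # 1: perfect independence
#' @export
chi2_pvalue <- function(a, b, c, d, correct = FALSE) {
  if (any(c(a, b, c, d) < 0)) stop("counts must be non-negative")
  n <- a + b + c + d
  if (n == 0) stop("empty table")
  n1 <- a + c; n0 <- b + d
  if (n1 == 0 || n0 == 0)
    stop("both class margins must be positive")
  m1 <- a + b; m0 <- c + d
  if (m1 == 0 || m0 == 0) return(1)
  num <- a * d - b * c
  if (correct) {
    num <- max(abs(num) - n / 2, 0)
    stat <- n * num^2 / (n1 * n0 * m1 * m0)
  } else {
    stat <- n * num^2 / (n1 * n0 * m1 * m0)
  }
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

# Vectorized minimum p-value over all thresholds for one distance profile.
# Thresholds are the observed distances themselves (duplicates collapsed);
# prediction is dist <= theta, so each distinct observed distance induces
# one split. Ties in p broken by the smallest theta. Returns list(p_min,
# theta, and the full per-threshold table at the optimum).
min_pvalue_profile <- function(dists, labels, correct = FALSE) {
  n <- length(dists)
  n1 <- sum(labels == 1L); n0 <- n - n1
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  ord <- order(dists)
  ds <- dists[ord]
  ys <- labels[ord]
  cum_a <- cumsum(ys == 1L)
  # last index of each tie group = the split induced by that threshold
  last <- which(ds != c(ds[-1L], NA) | seq_len(n) == n)
  a <- cum_a[last]
  m1 <- last                      # predicted positive count at threshold
  b <- m1 - a
  cc <- n1 - a
  dd <- n0 - b
  m0 <- n - m1
  stat <- ifelse(m0 == 0, 0, n * (a * dd - b * cc)^2 /
                   (as.double(n1) * n0 * m1 * pmax(m0, 1)))
  if (correct) {
    num <- pmax(abs(a * dd - b * cc) - n / 2, 0)
    stat <- ifelse(m0 == 0, 0, n * num^2 / (as.double(n1) * n0 * m1 * pmax(m0, 1)))
  }
  p <- ifelse(m0 == 0, 1, stats::pchisq(stat, df = 1, lower.tail = FALSE))
  best <- which.min(p)            # first minimum = smallest theta
  list(p_min = p[best], theta = ds[last[best]],
       a = a[best], b = b[best], c = cc[best], d = dd[best])
}

#' Minimum p-value of a shapelet candidate over all thresholds
#'
#' Computes the candidate's distance to every series, then evaluates the
#' chi-squared p-value at every threshold in the set of observed distances
#' (prediction uses `<= theta`, so each distinct observed distance induces
#' one split). Returns the minimizing p-value and threshold; ties in p are
#' broken by the smallest threshold.
#'
#' @param shapelet numeric vector, the candidate subsequence.
#' @param dataset a [series_dataset()] with both classes present.
#' @param correct Yates correction flag, see [chi2_pvalue()].
#' @return A list with `p_min`, `theta`, the optimal table counts
#'   (`a`, `b`, `c`, `d`) and the per-series `distances`.
#' @export
min_pvalue <- function(shapelet, dataset, correct = FALSE) {
  stopifnot(inherits(dataset, "series_dataset"))
  dists <- vapply(dataset$values, function(v)
    min_euclidean_distance(shapelet, v), numeric(1))
  out <- min_pvalue_profile(dists, dataset$labels, correct = correct)
  out$distances <- dists
  out
}

# Batch scoring of an extracted candidate set: p_min and theta for every
# row of `candidates`, using the vectorized distance machinery.
score_candidates <- function(candidates, dataset, correct = FALSE) {
  dmat <- candidate_distances(candidates, dataset)
  y <- dataset$labels
  k <- nrow(candidates)
  p_min <- numeric(k); theta <- numeric(k)
  tabs <- matrix(NA_real_, k, 4L)
  for (j in seq_len(k)) {
    r <- min_pvalue_profile(dmat[j, ], y, correct = correct)
    p_min[j] <- r$p_min; theta[j] <- r$theta
    tabs[j, ] <- c(r$a, r$b, r$c, r$d)
  }
  candidates$p_min <- p_min
  candidates$theta <- theta
  candidates$tab_a <- tabs[, 1L]; candidates$tab_b <- tabs[, 2L]
  candidates$tab_c <- tabs[, 3L]; candidates$tab_d <- tabs[, 4L]
  candidates
}

#' Bonferroni-corrected significance threshold
#'
#' Divides the target family-wise error rate by the total number of tests:
#' `n_candidates` candidate shapelets times `n` thresholds per candidate.
#'
#' @param alpha target FWER in (0, 1).
#' @param n_candidates number of candidate shapelets (positive).
#' @param n number of thresholds per candidate (the dataset size).
#' @return The corrected threshold `alpha / (n_candidates * n)`.
#' @export
bonferroni_threshold <- function(alpha, n_candidates, n) {
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must lie in (0, 1)")
  if (n_candidates < 1) stop("need at least one candidate")
  if (n < 1) stop("`n` must be positive")
  alpha / (n_candidates * n)
}

#' Tarone-corrected significance threshold
#'
#' Finds the largest threshold of the form `alpha / k` (k a positive
#' integer) such that at most `k` of the supplied minimum p-values fall
#' below it -- the fixed point reached by lowering the threshold from 1
#' while discounting untestable candidates. Never more conservative than
#' the Bonferroni threshold over the same candidates.
#'
#' @param p_mins numeric vector of per-candidate minimum p-values.
#' @param alpha target FWER in (0, 1).
#' @return A list with `delta` (the corrected threshold), `k` (the
#'   correction factor), and `testable` (logical vector, `p_mins < delta`).
#' @examples
#' tarone_threshold(c(0.001, 0.002, 0.01, 0.04, 0.2), 0.05)$delta  # 0.05/3
#' @export
tarone_threshold <- function(p_mins, alpha) {
  if (length(p_mins) == 0L) stop("`p_mins` must be non-empty")
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must lie in (0, 1)")
  ps <- sort(p_mins)
  m <- length(ps)
  k <- 1L
  repeat {
    n_below <- sum(ps < alpha / k)
    if (n_below <= k || k >= m) break
    k <- k + 1L
  }
  delta <- alpha / k
  list(delta = delta, k = k, testable = p_mins < delta)
}
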