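#' Map retrieved shapelets to their closest ground-truth prototypes
#'
#' Each retrieved shapelet is assigned to the prototype with the highest
#' similarity (ties to the lowest prototype index). The number of
#' correctly detected prototypes `k_d` is the number of distinct
#' prototypes in the image of that map.
#'
#' @param retrieved list of numeric vectors (the retrieved shapelets).
#' @param prototypes list of numeric vectors (the ground truth).
#' @return A data.frame with one row per retrieved shapelet: `retrieved`,
#'   `prototype` (index of the best match) and `similarity`.
#' @export
match_retrieved <- function(retrieved, prototypes) {
  if (length(retrieved) == 0L)
    return(data.frame(retrieved = integer(0), prototype = integer(0),
                      similarity = numeric(0)))
  rows <- lapply(seq_along(retrieved), function(i) {
    sims <- vapply(prototypes, function(p)
      shapelet_similarity(retrieved[[i]], p), numeric(1))
    best <- which.max(sims)   # first max = lowest prototype index
    data.frame(retrieved = i, prototype = best, similarity = sims[best])
  })
  do.call(rbind, rows)
}

#' Precision, recall and F1 of a retrieval
#'
#' `recall = k_d / n_truth`, `precision = k_d / n_retrieved`, and F1 their
#' harmonic mean. An empty retrieved set (or `k_d = 0`) scores 0 on
#' precision and F1 rather than erroring, so degenerate runs rank worst.
#'
#' @param k_d number of correctly detected prototypes.
#' @param n_truth number of ground-truth prototypes.
#' @param n_retrieved number of retrieved shapelets.
#' @return A list with `precision`, `recall`, `f1`.
#' @export
prf1 <- function(k_d, n_truth, n_retrieved) {
  recall <- if (n_truth > 0) k_d / n_truth else 0
  precision <- if (n_retrieved > 0) k_d / n_retrieved else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  list(precision = precision, recall = recall, f1 = f1)
}

#' Worst-case retrieval fidelity
#'
#' The minimum, over retrieved shapelets, of the similarity to their
#' best-matching prototype: low values mean at least one retrieved
#' shapelet is far from every ground-truth shape. Empty retrievals score 0.
#'
#' @inheritParams match_retrieved
#' @return Scalar in \[0, 1\].
#' @export
min_sim <- function(retrieved, prototypes) {
  m <- match_retrieved(retrieved, prototypes)
  if (nrow(m) == 0L) return(0)
  min(m$similarity)
}

#' Score a retrieval against ground-truth prototypes
#'
#' Convenience wrapper combining [match_retrieved()], [prf1()] and
#' [min_sim()] into one report.
#'
#' @param retrieved list of numeric vectors, or a `mining_result` (its
#'   significant shapelets are used).
#' @param prototypes list of ground-truth prototype vectors.
#' @return A list of class `evaluation_report`: `k_d`, `precision`,
#'   `recall`, `f1`, `min_sim`, `n_retrieved` and `per_prototype_hits`.
#' @export
evaluate_retrieval <- function(retrieved, prototypes) {
  if (inherits(retrieved, "mining_result"))
    retrieved <- retrieved$significant$values
  m <- match_retrieved(retrieved, prototypes)
  k_d <- length(unique(m$prototype))
  scores <- prf1(k_d, length(prototypes), length(retrieved))
  hits <- table(factor(m$prototype, levels = seq_along(prototypes)))
  structure(c(list(k_d = k_d), scores,
              list(min_sim = if (nrow(m)) min(m$similarity) else 0,
                   n_retrieved = length(retrieved),
                   per_prototype_hits = as.integer(hits))),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> k_d = %d of %d prototypes, %d retrieved\n",
              x$k_d, length(x$per_prototype_hits), x$n_retrieved))
  cat(sprintf("  precision %.3f, recall %.3f, F1 %.3f, min_sim %.3f\n",
              x$precision, x$recall, x$f1, x$min_sim))
  invisible(x)
}

#' Structural summary of a shapelet set
#'
#' Numeric summaries of a retrieved set's structure: per-shapelet variance
#' of values (flat shapelets have variance near 0), the distribution of
#' pairwise similarities within the set, and -- when p-values are supplied
#' -- their log10 distribution.
#'
#' @param values_list list of numeric shapelet vectors.
#' @param p_mins optional vector of the shapelets' minimum p-values.
#' @return A list with `variances`, `pairwise_similarities` (upper
#'   triangle, excluding the diagonal) and `log10_p_min` (or `NULL`).
#' @export
shapelet_set_stats <- function(values_list, p_mins = NULL) {
  k <- length(values_list)
  variances <- vapply(values_list, stats::var, numeric(1))
  pair <- numeric(0)
  if (k >= 2L) {
    sm <- similarity_matrix(values_list)
    pair <- sm[upper.tri(sm)]
  }
  list(variances = variances, pairwise_similarities = pair,
       log10_p_min = if (is.null(p_mins)) NULL else log10(p_mins))
}

#' Welch test between two methods' per-repetition scores
#'
#' Two-sided Welch two-sample t-test (unequal variances) on per-repetition
#' F1 scores (or any per-repetition metric) of two methods.
#'
#' @param x,y numeric vectors of per-repetition scores, each of length
#'   at least 2.
#' @return A list with `statistic`, `p_value`, `df` and the two means.
#' @export
compare_methods <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("need at least 2 repetitions per method for the Welch test")
  if (stats::sd(x) == 0 && stats::sd(y) == 0 && mean(x) == mean(y))
    return(list(statistic = 0, p_value = 1, df = NA_real_,
                mean_x = mean(x), mean_y = mean(y)))
  tt <- stats::t.test(x, y, var.equal = FALSE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), mean_x = mean(x), mean_y = mean(y))
}
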