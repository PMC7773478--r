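#' Labeled time-series dataset
#'
#' Container for a collection of univariate time series with binary
#' phenotype labels. Series may have different lengths (the SOFA-score and
#' vital-sign series this package targets are routinely ragged).
#'
#' @param values list of numeric vectors, one per series; each non-empty.
#' @param labels integer/numeric vector of 0/1 phenotype labels, one per
#'   series.
#' @param ids optional character vector of series identifiers; defaults to
#'   `"s1"`, `"s2"`, ...
#' @return An object of class `series_dataset`: a list with elements
#'   `values`, `labels` (integer), `ids` and `n`.
#' @examples
#' d <- series_dataset(list(c(1, 2, 3), c(0, 0)), labels = c(1, 0))
#' d$n
#' @export
series_dataset <- function(values, labels, ids = NULL) {
  if (!is.list(values) || length(values) == 0L)
    stop("`values` must be a non-empty list of numeric vectors")
  if (any(!vapply(values, is.numeric, logical(1))))
    stop("every series must be numeric")
  lens <- lengths(values)
  if (any(lens == 0L))
    stop("empty series at position(s): ", paste(which(lens == 0L), collapse = ", "))
  if (any(vapply(values, function(v) anyNA(v), logical(1))))
    stop("series values must not contain NA")
  if (length(labels) != length(values))
    stop("`labels` must have one entry per series")
  if (!all(labels %in% c(0, 1)))
    stop("labels must be binary 0/1")
  if (is.null(ids)) ids <- paste0("s", seq_along(values))
  if (anyDuplicated(ids)) stop("series ids must be unique")
  values <- lapply(values, as.numeric)
  structure(
    list(values = values, labels = as.integer(labels), ids = as.character(ids),
         n = length(values)),
    class = "series_dataset"
  )
}

#' @export
print.series_dataset <- function(x, ...) {
  lens <- lengths(x$values)
  cat(sprintf("<series_dataset> %d series (%d cases / %d controls), lengths %d-%d\n",
              x$n, sum(x$labels == 1L), sum(x$labels == 0L),
              min(lens), max(lens)))
  invisible(x)
}

#' Minimum Euclidean distance between two sequences
#'
#' The standard shapelet distance: the shorter sequence is slid along the
#' longer one and the minimum over all alignments of the Euclidean norm of
#' the pointwise difference is returned. Either argument may be the shorter
#' one; roles are assigned internally. For equal-length inputs there is a
#' single alignment and the distance is the plain Euclidean distance.
#'
#' This distance is not a metric (the triangle inequality fails), which is
#' one reason the package selects representatives by submodular subset
#' selection rather than by clustering.
#'
#' @param r,s numeric vectors, both non-empty.
#' @return A non-negative scalar; 0 iff the shorter sequence occurs exactly
#'   as a contiguous window of the longer one.
#' @examples
#' min_euclidean_distance(c(0, 0), c(0, 0, 1))   # 0: exact occurrence
#' min_euclidean_distance(c(1, 2), c(0, 0, 0))   # sqrt(5)
#' @export
min_euclidean_distance <- function(r, s) {
  if (length(r) == 0L || length(s) == 0L)
    stop("sequences must be non-empty")
  if (length(r) > length(s)) { tmp <- r; r <- s; s <- tmp }
  w <- length(r)
  n_off <- length(s) - w + 1L
  if (n_off == 1L) return(sqrt(sum((s - r)^2)))
  best <- Inf
  for (j in seq_len(n_off)) {
    d2 <- sum((s[j:(j + w - 1L)] - r)^2)
    if (d2 < best) best <- d2
  }
  sqrt(best)
}

#' Similarity transform of the shapelet distance
#'
#' `sim(r, s) = 1 / (1 + dist(r, s))`, mapping the unbounded minimum
#' Euclidean distance into (0, 1]; equals 1 iff the distance is 0.
#'
#' @inheritParams min_euclidean_distance
#' @return A scalar in (0, 1].
#' @export
shapelet_similarity <- function(r, s) {
  1 / (1 + min_euclidean_distance(r, s))
}

#' Predict a series label from a shapelet
#'
#' A shapelet is a pair (subsequence, threshold): a series is predicted
#' positive when it contains a window within distance `theta` of the
#' subsequence. The boundary is inclusive. The shapelet must not be longer
#' than the series, because the prediction semantics ("the shapelet occurs
#' in the series") is directional.
#'
#' @param shapelet numeric vector, the shapelet subsequence.
#' @param theta non-negative distance threshold.
#' @param series numeric vector, the series to classify.
#' @return 0 or 1 (integer).
#' @export
predict_shapelet <- function(shapelet, theta, series) {
  if (length(shapelet) > length(series))
    stop("shapelet is longer than the series; prediction is undefined")
  if (theta < 0) stop("`theta` must be non-negative")
  as.integer(min_euclidean_distance(shapelet, series) <= theta)
}

#' Extract shapelet candidates by sliding windows
#'
#' For every series and every requested window length `w` not exceeding the
#' series length, emits all contiguous windows with provenance. Output
#' order is deterministic: by series order, then window length ascending,
#' then start offset ascending. Start offsets are 0-based, windows
#' half-open `[start, start + w)`.
#'
#' @param dataset a [series_dataset()].
#' @param window_lengths integer vector of window widths, each >= 2.
#' @param dedup if `TRUE`, candidates with identical value sequences are
#'   collapsed to the first occurrence. Identical windows carry no extra
#'   statistical information and inflate the multiple-testing correction,
#'   so mining runs with dedup on; raw extraction defaults to off.
#' @return A data.frame with columns `source_id`, `series` (index into the
#'   dataset), `start` (0-based), `length`, and a list-column `values`.
#' @examples
#' d <- series_dataset(list(c(1, 1, 1, 1)), labels = 1)
#' nrow(extract_candidates(d, 2))               # 3 windows
#' nrow(extract_candidates(d, 2, dedup = TRUE)) # 1 after collapsing
#' @export
extract_candidates <- function(dataset, window_lengths, dedup = FALSE) {
  stopifnot(inherits(dataset, "series_dataset"))
  window_lengths <- sort(unique(as.integer(window_lengths)))
  if (length(window_lengths) == 0L) stop("empty window length set")
  if (any(window_lengths < 2L)) stop("window lengths must be >= 2")
  if (max(window_lengths) > max(lengths(dataset$values)))
    stop("window length exceeds the maximum series length")

  rows <- vector("list", 0L)
  k <- 0L
  for (i in seq_len(dataset$n)) {
    v <- dataset$values[[i]]
    m <- length(v)
    for (w in window_lengths) {
      if (w > m) next
      n_win <- m - w + 1L
      for (st in seq_len(n_win) - 1L) {
        k <- k + 1L
        rows[[k]] <- list(source_id = dataset$ids[[i]], series = i,
                          start = st, length = w,
                          values = v[(st + 1L):(st + w)])
      }
    }
  }
  out <- data.frame(
    source_id = vapply(rows, `[[`, character(1), "source_id"),
    series = vapply(rows, `[[`, integer(1), "series"),
    start = vapply(rows, `[[`, integer(1), "start"),
    length = vapply(rows, `[[`, integer(1), "length"),
    stringsAsFactors = FALSE
  )
  out$values <- lapply(rows, `[[`, "values")
  if (dedup && nrow(out) > 1L) {
    key <- vapply(out$values, function(v) paste(format(v, digits = 17), collapse = ","),
                  character(1))
    out <- out[!duplicated(key), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

# Min distance of every candidate (rows, all of width w) to every series:
# returns a k x n matrix. Vectorized per series via cross products.
candidate_distance_matrix <- function(cand_mat, dataset) {
  w <- ncol(cand_mat)
  k <- nrow(cand_mat)
  n <- dataset$n
  cn2 <- rowSums(cand_mat^2)
  out <- matrix(NA_real_, k, n)
  for (i in seq_len(n)) {
    v <- dataset$values[[i]]
    m <- length(v)
    if (w > m) stop("candidate longer than series ", dataset$ids[[i]])
    n_win <- m - w + 1L
    W <- matrix(NA_real_, n_win, w)
    for (j in seq_len(n_win)) W[j, ] <- v[j:(j + w - 1L)]
    wn2 <- rowSums(W^2)
    cross <- tcrossprod(cand_mat, W)          # k x n_win
    d2 <- sweep(-2 * cross, 2, wn2, "+") + cn2
    dmin <- d2[, 1L]
    if (n_win > 1L) for (j in 2L:n_win) dmin <- pmin(dmin, d2[, j])
    out[, i] <- sqrt(pmax(dmin, 0))
  }
  out
}

# Distance profiles for a mixed-length candidate set: k x n matrix.
candidate_distances <- function(candidates, dataset) {
  ws <- unique(candidates$length)
  out <- matrix(NA_real_, nrow(candidates), dataset$n)
  for (w in ws) {
    idx <- which(candidates$length == w)
    cm <- do.call(rbind, candidates$values[idx])
    out[idx, ] <- candidate_distance_matrix(cm, dataset)
  }
  out
}

#' Pairwise similarity matrix of a candidate set
#'
#' Computes `1 / (1 + dist)` for every pair of candidate subsequences,
#' where `dist` is the minimum Euclidean distance of
#' [min_euclidean_distance()]. Equal-length pairs use a fast Euclidean
#' path; unequal-length pairs slide the shorter over the longer. The
#' matrix is symmetric with unit diagonal and needs O(k^2) memory for k
#' candidates.
#'
#' @param values_list list of numeric vectors.
#' @return A k x k numeric matrix of similarities in (0, 1].
#' @export
similarity_matrix <- function(values_list) {
  k <- length(values_list)
  lens <- lengths(values_list)
  out <- matrix(NA_real_, k, k)
  diag(out) <- 1
  for (w1 in sort(unique(lens))) {
    i1 <- which(lens == w1)
    m1 <- do.call(rbind, values_list[i1])
    # same-length block: plain Euclidean distances
    if (length(i1) > 1L) {
      d <- as.matrix(stats::dist(m1))
      out[i1, i1] <- 1 / (1 + d)
    } else {
      out[i1, i1] <- 1
    }
    for (w2 in sort(unique(lens))) {
      if (w2 <= w1) next
      i2 <- which(lens == w2)
      m2 <- do.call(rbind, values_list[i2])
      n_off <- w2 - w1 + 1L
      c1n2 <- rowSums(m1^2)
      dmin <- NULL
      for (j in seq_len(n_off)) {
        sub <- m2[, j:(j + w1 - 1L), drop = FALSE]
        d2 <- outer(c1n2, rowSums(sub^2), "+") - 2 * tcrossprod(m1, sub)
        dmin <- if (is.null(dmin)) d2 else pmin(dmin, d2)
      }
      s <- 1 / (1 + sqrt(pmax(dmin, 0)))
      out[i1, i2] <- s
      out[i2, i1] <- t(s)
    }
  }
  out
}
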