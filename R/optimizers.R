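# Run `expr` under a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Exhaustive representative-subset selection (test oracle)
#'
#' Enumerates every subset of the ground set and returns the one
#' maximizing the mixture objective. Ties are broken by smaller set size,
#' then lexicographic order. Intended as a brute-force oracle for small
#' instances; refuses more than 14 items.
#'
#' @param S integer vector of item indices.
#' @param params a [mixture_params()].
#' @param sim similarity oracle (matrix or function).
#' @return Integer vector: the optimal subset (sorted).
#' @export
exhaustive_select <- function(S, params, sim) {
  k <- length(S)
  if (k > 14L) stop("exhaustive search refuses more than 14 items")
  best_obj <- -Inf; best <- integer(0)
  tol <- 1e-12
  for (mask in 0:(2^k - 1)) {
    R <- S[bitwAnd(mask, bitwShiftL(1L, seq_len(k) - 1L)) != 0L]
    obj <- mixture_objective(R, S, params, sim)
    better <- obj > best_obj + tol
    tie <- abs(obj - best_obj) <= tol &&
      (length(R) < length(best) ||
         (length(R) == length(best) && length(R) > 0L &&
            paste(sort(R), collapse = ",") < paste(sort(best), collapse = ",")))
    if (better || tie) { best_obj <- obj; best <- R }
  }
  sort(best)
}

#' Greedy representative-subset selection
#'
#' Starts from the empty set and repeatedly adds the item with the largest
#' positive marginal gain of the mixture objective, stopping when no item
#' improves it. Ties go to the earliest item. The objective is evaluated
#' from scratch for every candidate addition -- this is the classical
#' baseline whose cost the streaming optimizer [big_select()] improves on,
#' so no incremental caching is used here.
#'
#' @inheritParams exhaustive_select
#' @return Integer vector: the selected subset, in order of addition.
#' @export
greedy_select <- function(S, params, sim) {
  R <- integer(0)
  current <- mixture_objective(R, S, params, sim)
  remaining <- S
  while (length(remaining) > 0L) {
    gains <- vapply(remaining, function(s)
      mixture_objective(c(R, s), S, params, sim) - current, numeric(1))
    best <- which.max(gains)
    if (gains[best] <= 0) break
    R <- c(R, remaining[best])
    current <- current + gains[best]
    remaining <- remaining[-best]
  }
  R
}

#' Bidirectional greedy representative-subset selection
#'
#' Single pass over the ground set maintaining a growing set and a
#' shrinking set initialized to the full ground set. Each item is either
#' committed to the representative set or discarded from the shrinking
#' set, with probability proportional to the clipped marginal gains of the
#' two moves (both gains zero gives probability 0.5). Objectives are
#' evaluated from scratch over the fixed ground set, as the baseline is
#' defined. Reproducible given `seed`.
#'
#' @inheritParams exhaustive_select
#' @param seed integer RNG seed (default 0).
#' @return Integer vector: the selected subset, in order of commitment.
#' @export
bidirectional_greedy_select <- function(S, params, sim, seed = 0L) {
  with_seed(seed, {
    R <- integer(0)
    B <- S
    for (s in S) {
      a <- mixture_objective(c(R, s), S, params, sim) -
        mixture_objective(R, S, params, sim)
      b <- mixture_objective(setdiff(B, s), S, params, sim) -
        mixture_objective(B, S, params, sim)
      ap <- max(a, 0); bp <- max(b, 0)
      prob <- if (!is.finite(ap + bp) || ap + bp == 0) 0.5 else ap / (ap + bp)
      if (stats::runif(1) < prob) {
        R <- c(R, s)
      } else {
        B <- setdiff(B, s)
      }
    }
    R
  })
}

#' Streaming representative-subset selection (bidirectional iterative greedy)
#'
#' Processes the items of the ground set once, in the given order, through
#' [big_step()]: each item is assigned to the representative set or to the
#' discard set with probability proportional to the clipped marginal gains
#' of the mixture objective, evaluated against the ground set processed so
#' far via incremental O(items processed) cache updates. Reproducible
#' given `seed`.
#'
#' @inheritParams bidirectional_greedy_select
#' @param n_items total number of items the similarity oracle is indexed
#'   by; defaults to `max(S)`.
#' @return Integer vector: the representative set, in order of admission.
#' @export
big_select <- function(S, params, sim, seed = 0L, n_items = max(S)) {
  state <- rep_state_new(n_items, sim, params)
  with_seed(seed, {
    for (s in S) big_step(state, s)
  })
  S[state$in_R[S]]
}

#' Threshold representative-subset selection
#'
#' Classical single-pass baseline: an item becomes a representative iff
#' its similarity to every current representative is below `tau`. No
#' coverage/diversity trade-off and no approximation guarantee; included
#' as a comparison partner.
#'
#' @param S integer vector of item indices.
#' @param tau similarity cutoff in (0, 1).
#' @param sim similarity oracle (matrix or function).
#' @return Integer vector: the selected subset, in order of admission.
#' @export
threshold_select <- function(S, tau, sim) {
  if (tau <= 0 || tau >= 1) stop("`tau` must lie in (0, 1)")
  R <- integer(0)
  for (s in S) {
    if (length(R) == 0L || all(sim_lookup(sim, s, R) < tau)) R <- c(R, s)
  }
  R
}
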