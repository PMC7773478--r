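#' Parameters of the submodular mixture objective
#'
#' The representative-subset objective mixes a coverage term (facility
#' location) and a diversity term (sum redundancy), weighted by
#' `lambda_mix`, plus a modular size term `lambda_size * |R|`. The size
#' term is added with a positive sign, as the objective is written; the
#' effective per-item penalty comes from the self-pair on the diagonal of
#' the redundancy sum, which charges `(1 - lambda_mix)` for every item
#' admitted to R before any pairwise redundancy is counted. Setting
#' `size_penalty = TRUE` flips the size term to `-lambda_size * |R|` for
#' users who want an explicit cardinality penalty instead.
#'
#' @param lambda_mix weight of the facility-location term in \[0, 1\];
#'   default 0.5.
#' @param lambda_size weight of the size term; default 1.
#' @param size_penalty if `TRUE`, the size term enters with a negative
#'   sign. Default `FALSE` (the sign as the objective is written).
#' @return A list of class `mixture_params`.
#' @export
mixture_params <- function(lambda_mix = 0.5, lambda_size = 1,
                           size_penalty = FALSE) {
  if (lambda_mix < 0 || lambda_mix > 1) stop("`lambda_mix` must lie in [0, 1]")
  structure(list(lambda_mix = lambda_mix, lambda_size = lambda_size,
                 size_sign = if (size_penalty) -1 else 1),
            class = "mixture_params")
}

# Resolve a similarity oracle: either a k x k matrix or a function(i, j).
sim_lookup <- function(sim, i, j) {
  if (is.matrix(sim)) sim[i, j, drop = TRUE] else
    mapply(sim, rep_len(i, max(length(i), length(j))),
           rep_len(j, max(length(i), length(j))))
}

#' Facility-location objective
#'
#' Mean, over every item of the ground set `S`, of its best similarity to
#' the representative set `R`. Coverage term of the mixture objective:
#' monotone nondecreasing and submodular in `R`. The max over an empty `R`
#' is defined as 0, so `facility_location(integer(0), S, sim) == 0`.
#'
#' @param R integer vector of representative item indices, a subset of `S`.
#' @param S integer vector of ground-set item indices (non-empty).
#' @param sim similarity oracle: a symmetric matrix indexed by item, or a
#'   function of two indices.
#' @return Scalar in \[0, 1\].
#' @export
facility_location <- function(R, S, sim) {
  if (length(S) == 0L) stop("`S` must be non-empty")
  if (!all(R %in% S)) stop("`R` must be a subset of `S`")
  if (length(R) == 0L) return(0)
  best <- vapply(S, function(s) max(sim_lookup(sim, s, R)), numeric(1))
  mean(best)
}

#' Sum-redundancy objective
#'
#' Total pairwise similarity over the ground set minus total pairwise
#' similarity within the representative set. Both sums range over ordered
#' pairs including self-pairs (so each unordered pair counts twice and each
#' item contributes its unit self-similarity); any consistent convention
#' gives `R = S -> 0`, and this one is the cheapest to maintain
#' incrementally. Diversity term: monotone nonincreasing and submodular.
#'
#' @inheritParams facility_location
#' @return Non-negative scalar; 0 when `R == S`.
#' @export
sum_redundancy <- function(R, S, sim) {
  if (!all(R %in% S)) stop("`R` must be a subset of `S`")
  pair_sum <- function(idx) {
    if (length(idx) == 0L) return(0)
    if (is.matrix(sim)) return(sum(sim[idx, idx]))
    tot <- 0
    for (x in idx) tot <- tot + sum(sim_lookup(sim, x, idx))
    tot
  }
  pair_sum(S) - pair_sum(R)
}

#' Submodular mixture objective
#'
#' `lambda_mix * f_fl + (1 - lambda_mix) * f_sr + sign * lambda_size * |R|`
#' where the size-term sign is controlled by [mixture_params()].
#'
#' @inheritParams facility_location
#' @param params a [mixture_params()] object.
#' @return Scalar objective value.
#' @export
mixture_objective <- function(R, S, params, sim) {
  stopifnot(inherits(params, "mixture_params"))
  params$lambda_mix * facility_location(R, S, sim) +
    (1 - params$lambda_mix) * sum_redundancy(R, S, sim) +
    params$size_sign * params$lambda_size * length(R)
}

#' Create an incremental representative-selection state
#'
#' Holds the growing representative set `R_hat`, the non-representative set
#' `B`, and the cached quantities that let the streaming optimizer update
#' the facility-location and sum-redundancy values in O(processed items)
#' work per step instead of recomputing the O(k^2) double sums: per-item
#' best similarity to `R_hat` and to `B`, and running ordered-pair
#' similarity totals. The pairwise-similarity cache over processed items
#' needs O(k^2) memory.
#'
#' @param n_items total number of items that may be processed.
#' @param sim similarity oracle: a symmetric `n_items` x `n_items` matrix,
#'   or a function of two indices (cached lazily as items arrive).
#' @param params a [mixture_params()] object.
#' @return An environment of class `rep_state`.
#' @export
rep_state_new <- function(n_items, sim, params = mixture_params()) {
  stopifnot(inherits(params, "mixture_params"))
  st <- new.env(parent = emptyenv())
  st$n_items <- as.integer(n_items)
  st$params <- params
  if (is.matrix(sim)) {
    st$simc <- sim
    st$sim_fun <- NULL
  } else {
    st$simc <- matrix(NA_real_, n_items, n_items)
    diag(st$simc) <- 1
    st$sim_fun <- sim
  }
  st$S <- integer(0)          # processed items, in arrival order
  st$in_R <- logical(n_items)
  st$processed <- logical(n_items)
  st$fl_R <- numeric(n_items) # best similarity of each processed item to R_hat
  st$fl_B <- numeric(n_items) # best similarity of each processed item to B
  st$sr_total <- 0            # ordered-pair sum over processed items
  st$sr_R <- 0                # ordered-pair sum within R_hat
  st$sr_B <- 0                # ordered-pair sum within B
  st$sim_evals <- 0L          # operation counter (similarity lookups)
  class(st) <- c("rep_state", "environment")
  st
}

#' @export
print.rep_state <- function(x, ...) {
  cat(sprintf("<rep_state> %d processed: |R_hat| = %d, |B| = %d\n",
              length(x$S), sum(x$in_R), sum(x$processed & !x$in_R)))
  invisible(x)
}

#' Representative and non-representative item sets of a state
#' @param state a `rep_state`.
#' @return Integer vector of item indices.
#' @export
rep_state_R <- function(state) which(state$in_R)

#' @rdname rep_state_R
#' @export
rep_state_B <- function(state) which(state$processed & !state$in_R)

# Similarity of item i to all previously processed items, via the cache.
state_sim_row <- function(state, i) {
  S <- state$S
  if (length(S) == 0L) return(numeric(0))
  row <- state$simc[i, S]
  if (!is.null(state$sim_fun)) {
    miss <- which(is.na(row))
    if (length(miss)) {
      vals <- vapply(S[miss], function(j) state$sim_fun(i, j), numeric(1))
      row[miss] <- vals
      state$simc[i, S[miss]] <- vals
      state$simc[S[miss], i] <- vals
    }
  }
  state$sim_evals <- state$sim_evals + length(S)
  row
}

# Mixture objective of the current R_hat (or B) over the processed ground
# set, straight from the caches. Used by tests against scratch recomputes.
state_objective <- function(state, side = c("R", "B")) {
  side <- match.arg(side)
  p <- state$params
  S <- state$S
  nS <- length(S)
  if (nS == 0L) return(0)
  if (side == "R") {
    ffl <- sum(state$fl_R[S]) / nS
    fsr <- state$sr_total - state$sr_R
    sz <- sum(state$in_R)
  } else {
    ffl <- sum(state$fl_B[S]) / nS
    fsr <- state$sr_total - state$sr_B
    sz <- sum(state$processed & !state$in_R)
  }
  p$lambda_mix * ffl + (1 - p$lambda_mix) * fsr +
    p$size_sign * p$lambda_size * sz
}

#' One streaming step of the bidirectional iterative greedy optimizer
#'
#' Processes a new item: it is provisionally appended to the
#' non-representative set `B`, the marginal gains of (a) adding it to
#' `R_hat` and (b) removing it again from `B` are computed against the
#' current ground set using the incremental caches, clipped at zero, and
#' the item moves to `R_hat` with probability `a / (a + b)` (0.5 when both
#' clipped gains vanish). The add-side gain is evaluated on the ground set
#' including the new item; the remove-side compares the objective over the
#' ground set without the item against the one including it, since
#' removing the item shrinks the effective ground set.
#'
#' @param state a [rep_state_new()] environment (modified in place).
#' @param i index of the new, not yet processed item.
#' @param u optional uniform draw in \[0, 1\) overriding the RNG (for
#'   deterministic replay); by default drawn from the session RNG.
#' @return The state, invisibly, with attribute fields `last_p` (the move
#'   probability) and `last_accept` updated.
#' @export
big_step <- function(state, i, u = NULL) {
  stopifnot(inherits(state, "rep_state"))
  if (state$processed[i]) stop("item ", i, " was already processed")
  p <- state$params
  lm <- p$lambda_mix; ls <- p$lambda_size * p$size_sign
  S <- state$S
  nS_old <- length(S)
  nS_new <- nS_old + 1L

  row <- state_sim_row(state, i)
  R <- which(state$in_R)
  inR_S <- state$in_R[S]
  sum_all <- sum(row)
  sum_R <- sum(row[inR_S])
  sum_B <- sum_all - sum_R
  max_R <- if (length(R)) max(row[inR_S]) else 0
  max_B <- if (nS_old - length(R) > 0L) max(row[!inR_S]) else 0
  nR <- length(R)
  nB <- nS_old - nR

  sr_total_new <- state$sr_total + 2 * sum_all + 1

  # add side: ground set includes the new item, normalization nS_new
  flR_S <- state$fl_R[S]
  ffl_with <- (sum(pmax(flR_S, row)) + 1) / nS_new
  ffl_without <- (sum(flR_S) + max_R) / nS_new
  f_add <- lm * ffl_with +
    (1 - lm) * (sr_total_new - (state$sr_R + 2 * sum_R + 1)) +
    ls * (nR + 1)
  f_keep <- lm * ffl_without +
    (1 - lm) * (sr_total_new - state$sr_R) +
    ls * nR
  a <- f_add - f_keep

  # remove side: f(B without s) vs f(B with s), both against the current
  # (post-append) ground set; only the facility-location mean is
  # normalized by the respective set size (nS_old vs nS_new)
  flB_S <- state$fl_B[S]
  fB_without <- lm * (if (nS_old == 0L) 0 else sum(flB_S) / nS_old) +
    (1 - lm) * (sr_total_new - state$sr_B) +
    ls * nB
  fB_with <- lm * (sum(pmax(flB_S, row)) + 1) / nS_new +
    (1 - lm) * (sr_total_new - (state$sr_B + 2 * sum_B + 1)) +
    ls * (nB + 1)
  b <- fB_without - fB_with

  ap <- max(a, 0); bp <- max(b, 0)
  prob <- if (!is.finite(ap + bp) || ap + bp == 0) 0.5 else ap / (ap + bp)
  if (is.null(u)) u <- stats::runif(1)
  accept <- u < prob

  if (accept) {
    state$fl_R[S] <- pmax(flR_S, row)
    state$fl_R[i] <- 1
    state$fl_B[i] <- max_B
    state$sr_R <- state$sr_R + 2 * sum_R + 1
    state$in_R[i] <- TRUE
  } else {
    state$fl_B[S] <- pmax(flB_S, row)
    state$fl_B[i] <- 1
    state$fl_R[i] <- max_R
    state$sr_B <- state$sr_B + 2 * sum_B + 1
  }
  state$sr_total <- sr_total_new
  state$processed[i] <- TRUE
  state$S <- c(S, i)
  state$last_p <- prob
  state$last_accept <- accept
  invisible(state)
}

# Move a representative to B (used when the significance threshold drops
# and a member becomes untestable). The max-to-R cache cannot be patched
# after a removal, so it is rebuilt from the cached pairwise similarities;
# evictions are rare relative to stream steps.
state_evict <- function(state, i) {
  stopifnot(state$in_R[i])
  S <- state$S
  row <- state$simc[i, S]
  inR_S_old <- state$in_R[S]
  state$in_R[i] <- FALSE
  R_new <- which(state$in_R)
  state$sr_R <- state$sr_R - (2 * sum(row[inR_S_old & S != i]) + 1)
  B_old <- S[!inR_S_old & S != i]
  state$sr_B <- state$sr_B + 2 * sum(state$simc[i, B_old]) + 1
  if (length(R_new) == 0L) {
    state$fl_R[S] <- 0
  } else {
    sub <- state$simc[S, R_new, drop = FALSE]
    state$fl_R[S] <- apply(sub, 1L, max)
  }
  state$fl_B[S] <- pmax(state$fl_B[S], row)
  state$fl_B[i] <- 1
  invisible(state)
}
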