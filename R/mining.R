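# Shared front-end of all pipelines: extract, score, order by minimum
# p-value (stable on extraction order), and build the candidate
# similarity matrix.
prepare_mining <- function(dataset, window_lengths, dedup = TRUE,
                           correct = FALSE) {
  stopifnot(inherits(dataset, "series_dataset"))
  if (length(unique(dataset$labels)) < 2L)
    stop("both classes must be present for mining")
  cand <- extract_candidates(dataset, window_lengths, dedup = dedup)
  sc <- score_candidates(cand, dataset, correct = correct)
  ord <- order(sc$p_min, seq_len(nrow(sc)))
  list(scored = sc, p_order = ord,
       simmat = similarity_matrix(sc$values))
}

new_mining_result <- function(method, dataset, prep, keep, delta, alpha,
                              params, seed, counts, config_extra = list()) {
  sc <- prep$scored
  sig <- sc[keep, , drop = FALSE]
  sig <- sig[order(sig$p_min, seq_len(nrow(sig))), , drop = FALSE]
  rownames(sig) <- NULL
  structure(list(
    method = method,
    significant = sig,
    delta = delta,
    alpha = alpha,
    seed = seed,
    candidate_count = nrow(sc),
    n = dataset$n,
    counts = counts,
    config = c(list(alpha = alpha, seed = seed,
                    lambda_mix = params$lambda_mix,
                    lambda_size = params$lambda_size,
                    size_sign = params$size_sign),
               config_extra)
  ), class = "mining_result")
}

#' @export
print.mining_result <- function(x, ...) {
  cat(sprintf("<mining_result: %s> %d significant shapelet(s) of %d candidates\n",
              x$method, nrow(x$significant), x$candidate_count))
  cat(sprintf("  corrected threshold %.3g (target FWER %.3g), seed %d\n",
              x$delta, x$alpha, x$seed))
  if (nrow(x$significant) > 0L) {
    show <- utils::head(x$significant[, c("source_id", "start", "length",
                                          "theta", "p_min")], 10L)
    print(show)
  }
  invisible(x)
}

# The interleaved mining loop: stream candidates in ascending minimum
# p-value; each one is first classified representative / non-representative
# (by the streaming submodular optimizer, or by the threshold rule), and
# only representatives enter the testable count. delta is lowered to
# alpha / |R_hat| after every admission and members whose p-value no longer
# clears it are evicted to B, largest p-value first, never to return.
# Candidates whose p-value fails the current delta are untestable and are
# never processed; since the stream is sorted this permits exiting early.
s5m_core <- function(dataset, prep, alpha, params, seed,
                     rep_rule = c("big", "threshold"), tau = NULL,
                     early_exit = TRUE, method_name = "s5m") {
  rep_rule <- match.arg(rep_rule)
  sc <- prep$scored
  ord <- prep$p_order
  k <- nrow(sc)
  p_sorted <- sc$p_min[ord]

  with_seed(seed, {
    if (rep_rule == "threshold" && is.null(tau)) tau <- stats::runif(1)
    state <- if (rep_rule == "big")
      rep_state_new(k, prep$simmat, params) else NULL
    R <- integer(0)                 # candidate indices (into sc) in R_hat
    delta <- 1
    n_nonrep <- 0L; n_evict <- 0L; n_skipped <- 0L
    for (pos in seq_len(k)) {
      i <- ord[pos]
      if (p_sorted[pos] >= delta) {
        if (early_exit) {
          n_skipped <- k - pos + 1L
          break
        }
        n_skipped <- n_skipped + 1L
        next
      }
      if (rep_rule == "big") {
        big_step(state, i)
        accepted <- state$last_accept
      } else {
        accepted <- length(R) == 0L || all(prep$simmat[i, R] < tau)
      }
      if (!accepted) { n_nonrep <- n_nonrep + 1L; next }
      R <- c(R, i)
      delta <- min(delta, alpha / length(R))
      bad <- R[sc$p_min[R] >= delta]
      if (length(bad) > 0L) {
        bad <- bad[order(-sc$p_min[bad])]   # largest p first
        for (j in bad) {
          if (rep_rule == "big") state_evict(state, j)
          R <- setdiff(R, j)
          n_evict <- n_evict + 1L
        }
      }
    }
    if (length(R) == 0L) delta <- min(delta, alpha)
    new_mining_result(
      method_name, dataset, prep, keep = sort(R), delta = delta,
      alpha = alpha, params = params, seed = seed,
      counts = list(nonrepresentative = n_nonrep, evicted = n_evict,
                    pruned_untestable = n_skipped),
      config_extra = list(rep_rule = rep_rule, tau = tau,
                          early_exit = early_exit)
    )
  })
}

#' Mine representative, statistically significant shapelets (S5M)
#'
#' The interleaved pipeline: sliding-window candidates are scored by their
#' minimum chi-squared p-value over all distance thresholds, sorted, and
#' streamed through the bidirectional iterative greedy optimizer. A
#' candidate declared non-representative joins the discard set and never
#' counts toward the multiple-testing correction; a representative one
#' enters the testable set, the Tarone threshold drops to
#' `alpha / |R_hat|`, and members that no longer clear it are evicted. The
#' stream stops as soon as the next candidate's p-value fails the current
#' threshold. Because only representatives are counted, the correction
#' factor stays small and the procedure retains power where a correction
#' over all candidates collapses.
#'
#' @param dataset a [series_dataset()] with both classes present.
#' @param window_lengths integer vector of sliding-window widths.
#' @param alpha target family-wise error rate; default 0.05.
#' @param params a [mixture_params()].
#' @param seed integer seed for the run RNG (stochastic representativeness
#'   decisions); default 0.
#' @param dedup collapse duplicate candidate windows before testing
#'   (default `TRUE` for mining).
#' @param correct Yates continuity correction for the chi-squared test.
#' @param early_exit stop the stream at the first untestable candidate
#'   (identical result either way; default `TRUE`).
#' @return A `mining_result`: the significant set (with per-shapelet
#'   threshold `theta` and `p_min`), the final corrected threshold
#'   `delta`, candidate and rejection counts, and the full run
#'   configuration.
#' @seealso [tarone_submodular()], [bonferroni_submodular()],
#'   [feature_selection_tarone()], [s5m_threshold()] for the comparison
#'   pipelines, and [mine_shapelets()] for a single dispatcher.
#' @export
s5m_mine <- function(dataset, window_lengths, alpha = 0.05,
                     params = mixture_params(), seed = 0L, dedup = TRUE,
                     correct = FALSE, early_exit = TRUE) {
  prep <- prepare_mining(dataset, window_lengths, dedup, correct)
  s5m_core(dataset, prep, alpha, params, seed, rep_rule = "big",
           early_exit = early_exit, method_name = "s5m")
}

#' S5M with threshold-rule representativeness
#'
#' Same interleaved loop as [s5m_mine()], but a candidate is declared
#' representative iff its similarity to every current representative is
#' below `tau`. When `tau` is `NULL` it is drawn once per run, uniformly
#' on (0, 1), from the run RNG.
#'
#' @inheritParams s5m_mine
#' @param tau similarity cutoff in (0, 1), or `NULL` to draw it randomly.
#' @return A `mining_result`.
#' @export
s5m_threshold <- function(dataset, window_lengths, alpha = 0.05,
                          params = mixture_params(), seed = 0L,
                          dedup = TRUE, correct = FALSE, tau = NULL,
                          early_exit = TRUE) {
  prep <- prepare_mining(dataset, window_lengths, dedup, correct)
  s5m_core(dataset, prep, alpha, params, seed, rep_rule = "threshold",
           tau = tau, early_exit = early_exit, method_name = "s5m_threshold")
}

#' Two-stage pipeline: Tarone testing, then representative selection
#'
#' Stage 1 applies the Tarone-corrected threshold over the full candidate
#' set; stage 2 selects representatives among the significant candidates
#' with the streaming submodular optimizer (ascending p-value order).
#'
#' @inheritParams s5m_mine
#' @return A `mining_result`; `delta` is the stage-1 Tarone threshold.
#' @export
tarone_submodular <- function(dataset, window_lengths, alpha = 0.05,
                              params = mixture_params(), seed = 0L,
                              dedup = TRUE, correct = FALSE) {
  prep <- prepare_mining(dataset, window_lengths, dedup, correct)
  sc <- prep$scored
  tt <- tarone_threshold(sc$p_min, alpha)
  sig <- prep$p_order[sc$p_min[prep$p_order] < tt$delta]
  R <- if (length(sig) > 0L)
    big_select(sig, params, prep$simmat, seed = seed, n_items = nrow(sc))
  else integer(0)
  new_mining_result("tarone_submodular", dataset, prep, keep = sort(R),
                    delta = tt$delta, alpha = alpha, params = params,
                    seed = seed,
                    counts = list(significant_stage1 = length(sig),
                                  nonrepresentative = length(sig) - length(R)),
                    config_extra = list(tarone_k = tt$k))
}

#' Two-stage pipeline: Bonferroni testing, then representative selection
#'
#' Stage 1 keeps candidates whose minimum p-value clears the Bonferroni
#' threshold `alpha / (candidates x thresholds)`; stage 2 selects
#' representatives among the survivors with the streaming submodular
#' optimizer.
#'
#' @inheritParams s5m_mine
#' @return A `mining_result`; `delta` is the Bonferroni threshold.
#' @export
bonferroni_submodular <- function(dataset, window_lengths, alpha = 0.05,
                                  params = mixture_params(), seed = 0L,
                                  dedup = TRUE, correct = FALSE) {
  prep <- prepare_mining(dataset, window_lengths, dedup, correct)
  sc <- prep$scored
  delta <- bonferroni_threshold(alpha, nrow(sc), dataset$n)
  sig <- prep$p_order[sc$p_min[prep$p_order] < delta]
  R <- if (length(sig) > 0L)
    big_select(sig, params, prep$simmat, seed = seed, n_items = nrow(sc))
  else integer(0)
  new_mining_result("bonferroni_submodular", dataset, prep, keep = sort(R),
                    delta = delta, alpha = alpha, params = params,
                    seed = seed,
                    counts = list(significant_stage1 = length(sig),
                                  nonrepresentative = length(sig) - length(R)))
}

#' Two-stage pipeline: representative selection first, then Tarone testing
#'
#' Stage 1 selects representatives from all candidates, in extraction
#' order and irrespective of the class labels; stage 2 restricts Tarone
#' testing to the representatives. Selecting representatives first tends
#' to capture the structure of the whole dataset rather than the
#' label-associated diversity, which costs recall.
#'
#' @inheritParams s5m_mine
#' @return A `mining_result`; `delta` is the stage-2 Tarone threshold over
#'   the representatives.
#' @export
feature_selection_tarone <- function(dataset, window_lengths, alpha = 0.05,
                                     params = mixture_params(), seed = 0L,
                                     dedup = TRUE, correct = FALSE) {
  prep <- prepare_mining(dataset, window_lengths, dedup, correct)
  sc <- prep$scored
  reps <- big_select(seq_len(nrow(sc)), params, prep$simmat, seed = seed,
                     n_items = nrow(sc))
  if (length(reps) > 0L) {
    tt <- tarone_threshold(sc$p_min[reps], alpha)
    keep <- reps[sc$p_min[reps] < tt$delta]
    delta <- tt$delta
  } else {
    keep <- integer(0)
    delta <- alpha
  }
  new_mining_result("feature_selection_tarone", dataset, prep,
                    keep = sort(keep), delta = delta, alpha = alpha,
                    params = params, seed = seed,
                    counts = list(representatives_stage1 = length(reps),
                                  nonrepresentative = nrow(sc) - length(reps)))
}

#' Run any of the five mining pipelines
#'
#' Dispatcher over [s5m_mine()] and its four comparison pipelines; all
#' share candidate extraction, scoring and the similarity oracle, so
#' results are comparable under common seeds.
#'
#' @inheritParams s5m_mine
#' @param method one of `"s5m"`, `"tarone_submodular"`,
#'   `"bonferroni_submodular"`, `"feature_selection_tarone"`,
#'   `"s5m_threshold"`.
#' @param tau similarity cutoff for `"s5m_threshold"` (`NULL` draws it
#'   uniformly at random from the run RNG).
#' @return A `mining_result`.
#' @export
mine_shapelets <- function(dataset, window_lengths,
                           method = c("s5m", "tarone_submodular",
                                      "bonferroni_submodular",
                                      "feature_selection_tarone",
                                      "s5m_threshold"),
                           alpha = 0.05, params = mixture_params(),
                           seed = 0L, dedup = TRUE, correct = FALSE,
                           tau = NULL) {
  method <- match.arg(method)
  switch(method,
    s5m = s5m_mine(dataset, window_lengths, alpha, params, seed, dedup,
                   correct),
    tarone_submodular = tarone_submodular(dataset, window_lengths, alpha,
                                          params, seed, dedup, correct),
    bonferroni_submodular = bonferroni_submodular(dataset, window_lengths,
                                                  alpha, params, seed,
                                                  dedup, correct),
    feature_selection_tarone = feature_selection_tarone(dataset,
                                                        window_lengths,
                                                        alpha, params, seed,
                                                        dedup, correct),
    s5m_threshold = s5m_threshold(dataset, window_lengths, alpha, params,
                                  seed, dedup, correct, tau = tau)
  )
}
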