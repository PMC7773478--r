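#' The five ground-truth prototype subsequences
#'
#' Five structurally distinct shapes -- ramp up, ramp down, peak, valley,
#' step -- expressed as zero-centered deviations spanning
#' `[-amplitude/2, +amplitude/2]`. Centering matters: the simulated series
#' ride on the same zero baseline as the uniform noise background, so a
#' prototype window is closer to pure-noise controls than to cases
#' carrying a *different* prototype, and each shape is separately (not
#' collectively) associated with the phenotype. The default range of 10
#' mirrors the dynamic range of a clinical severity score. All pairwise
#' similarities are far below 1; the simulation machinery only relies on
#' this distinctness, so the set can be replaced by any list of user
#' prototypes.
#'
#' @param length prototype length in time points (default 10).
#' @param amplitude total value range of the shapes (default 10, i.e.
#'   values in \[-5, 5\]).
#' @return A named list of 5 numeric vectors.
#' @examples
#' p <- make_prototype_set()
#' round(shapelet_similarity(p$ramp_up, p$ramp_down), 3)
#' @export
make_prototype_set <- function(length = 10L, amplitude = 10) {
  length <- as.integer(length)
  if (length < 4L) stop("prototypes need at least 4 points")
  t01 <- seq(0, 1, length.out = length)
  half <- length %/% 2L
  a <- amplitude / 2
  list(
    ramp_up = a * (2 * t01 - 1),
    ramp_down = a * (1 - 2 * t01),
    peak = a * (1 - 2 * abs(2 * t01 - 1)),
    valley = a * (2 * abs(2 * t01 - 1) - 1),
    step = a * rep(c(-1, 1), c(half, length - half))
  )
}

#' Specification of a simulation design
#'
#' Bundles the parameters of the two planted-prototype designs: the
#' replication design (noisy copies of each prototype, no labels; used to
#' compare subset-selection optimizers) and the classification design
#' (prototypes injected into case series over a noise background, controls
#' pure noise; used to compare mining pipelines).
#'
#' @param prototypes list of numeric prototype subsequences; default
#'   [make_prototype_set()].
#' @param n_per_prototype replicates per prototype (replication design).
#' @param n_series total number of series (classification design).
#' @param sigma uniform noise amplitude: every noise value is drawn from
#'   Uniform(-sigma, sigma). Applied both to the injected prototype and to
#'   the background/control noise.
#' @param series_length length m of each generated series (classification
#'   design); default 20.
#' @param case_fraction fraction of series that are cases; default 0.5.
#' @param seed RNG seed making the generated data reproducible.
#' @return A list of class `simulation_spec`.
#' @export
simulation_spec <- function(prototypes = make_prototype_set(),
                            n_per_prototype = 10L, n_series = 100L,
                            sigma = 1, series_length = 20L,
                            case_fraction = 0.5, seed = 0L) {
  if (sigma < 0) stop("`sigma` must be non-negative")
  if (case_fraction <= 0 || case_fraction >= 1)
    stop("`case_fraction` must lie in (0, 1)")
  if (max(lengths(prototypes)) > series_length)
    stop("prototype longer than `series_length`")
  structure(list(prototypes = prototypes,
                 n_per_prototype = as.integer(n_per_prototype),
                 n_series = as.integer(n_series), sigma = sigma,
                 series_length = as.integer(series_length),
                 case_fraction = case_fraction, seed = as.integer(seed)),
            class = "simulation_spec")
}

runif_noise <- function(n, sigma) {
  if (sigma == 0) rep(0, n) else stats::runif(n, -sigma, sigma)
}

#' Generate noisy replicates of the prototypes
#'
#' Each output sequence is one prototype with i.i.d. Uniform(-sigma,
#' sigma) noise added per point; `n_per_prototype` copies are produced per
#' prototype, cycling through the prototypes.
#'
#' @param spec a [simulation_spec()].
#' @return A list with `sequences` (list of numeric vectors) and
#'   `prototype` (integer vector: which prototype each replicate copies).
#' @export
generate_replicates <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  with_seed(spec$seed, {
    n_proto <- length(spec$prototypes)
    proto_idx <- rep(seq_len(n_proto), times = spec$n_per_prototype)
    sequences <- lapply(proto_idx, function(k) {
      p <- spec$prototypes[[k]]
      p + runif_noise(length(p), spec$sigma)
    })
    list(sequences = sequences, prototype = proto_idx)
  })
}

#' Generate a labeled planted-shapelet dataset
#'
#' Case series (label 1) consist of a Uniform(-sigma, sigma) noise
#' background of length `series_length` with one noisy prototype injected
#' at a uniformly random offset (the injected window replaces the
#' background there); control series (label 0) are pure noise. Prototypes
#' are assigned to cases in round-robin order so every prototype is
#' planted equally often. Cases precede controls in the dataset.
#'
#' @param spec a [simulation_spec()].
#' @return A list with `dataset` (a [series_dataset()]) and `annotation`
#'   (data.frame: `series`, `id`, `label`, `prototype` index and 0-based
#'   injection `offset`, `NA` for controls).
#' @export
generate_labeled_dataset <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  with_seed(spec$seed, {
    n <- spec$n_series
    m <- spec$series_length
    n_case <- round(n * spec$case_fraction)
    if (n_case < 1L || n_case >= n)
      stop("`case_fraction` leaves an empty class")
    n_proto <- length(spec$prototypes)
    values <- vector("list", n)
    labels <- integer(n)
    proto <- rep(NA_integer_, n)
    offset <- rep(NA_integer_, n)
    for (i in seq_len(n_case)) {
      k <- ((i - 1L) %% n_proto) + 1L
      p <- spec$prototypes[[k]]
      w <- length(p)
      off <- sample.int(m - w + 1L, 1L) - 1L
      v <- runif_noise(m, spec$sigma)
      v[(off + 1L):(off + w)] <- p + runif_noise(w, spec$sigma)
      values[[i]] <- v
      labels[i] <- 1L
      proto[i] <- k
      offset[i] <- off
    }
    for (i in (n_case + 1L):n) {
      values[[i]] <- runif_noise(m, spec$sigma)
      labels[i] <- 0L
    }
    ds <- series_dataset(values, labels)
    list(dataset = ds,
         annotation = data.frame(series = seq_len(n), id = ds$ids,
                                 label = labels, prototype = proto,
                                 offset = offset))
  })
}
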