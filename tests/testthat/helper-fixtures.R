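# Shared fixtures and independent oracles, built in code.

# Brute-force sliding minimum Euclidean distance (independent of the
# package's implementation path).
brute_min_dist <- function(r, s) {
  if (length(r) > length(s)) { tmp <- r; r <- s; s <- tmp }
  w <- length(r)
  min(vapply(seq_len(length(s) - w + 1L), function(j)
    sqrt(sum((s[j:(j + w - 1L)] - r)^2)), numeric(1)))
}

# Brute-force minimum p-value: explicit double loop over thresholds and
# tables, chi2 p from R's distribution function.
brute_min_pvalue <- function(d, y) {
  best <- Inf; bt <- NA_real_
  n <- length(d); n1 <- sum(y == 1); n0 <- n - n1
  for (th in sort(unique(d))) {
    pred <- as.integer(d <= th)
    a <- sum(pred == 1 & y == 1); b <- sum(pred == 1 & y == 0)
    cc <- n1 - a; dd <- n0 - b
    if ((a + b) == 0 || (cc + dd) == 0) { p <- 1 }
    else {
      stat <- n * (a * dd - b * cc)^2 /
        (as.double(n1) * n0 * (a + b) * (cc + dd))
      p <- pchisq(stat, df = 1, lower.tail = FALSE)
    }
    if (p < best - 1e-15) { best <- p; bt <- th }
  }
  list(p_min = best, theta = bt)
}

# Small labeled dataset with one planted, perfectly separating window.
toy_planted_dataset <- function(n = 40, seed = 99, m = 12, amp = 8) {
  set.seed(seed)
  shape <- amp * c(-0.5, -0.3, 0, 0.4, 0.5, -0.5)
  vals <- vector("list", n)
  labs <- rep(0:1, length.out = n)
  for (i in seq_len(n)) {
    v <- runif(m, -0.5, 0.5)
    if (labs[i] == 1) {
      off <- sample.int(m - length(shape) + 1L, 1L)
      v[off:(off + length(shape) - 1L)] <- shape + runif(length(shape), -0.1, 0.1)
    }
    vals[[i]] <- v
  }
  series_dataset(vals, labs)
}

# Random similarity matrix for optimizer tests: symmetric, unit diagonal,
# values in (0, 1).
random_sim_matrix <- function(k, seed) {
  set.seed(seed)
  m <- matrix(runif(k * k, 0.02, 0.95), k, k)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  diag(m) <- 1
  m
}
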