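test_that("contingency table cross-tabulates predictions against labels", {
  d <- series_dataset(list(c(0, 0.1), c(0, 0.2), c(0, 0.9), c(0, 1)),
                      labels = c(1, 1, 0, 0))
  tb <- contingency_table(c(0, 0), 0.5, d)
  expect_equal(tb, list(a = 2L, b = 0L, c = 0L, d = 2L))
  # theta below every distance: nothing predicted positive
  tb0 <- contingency_table(c(5, 5), 0.01, d)
  expect_equal(tb0, list(a = 0L, b = 0L, c = 2L, d = 2L))
  # theta above every distance: everything predicted positive
  tb1 <- contingency_table(c(0, 0), 100, d)
  expect_equal(tb1, list(a = 2L, b = 2L, c = 0L, d = 0L))
  d1 <- series_dataset(list(1:2, 2:3), labels = c(1, 1))
  expect_error(contingency_table(c(1, 2), 1, d1), "both classes")
})

test_that("chi-squared p-value matches the closed form and R's test", {
  expect_equal(chi2_pvalue(5, 5, 5, 5), 1)
  expect_equal(chi2_pvalue(10, 0, 0, 10),
               pchisq(20, df = 1, lower.tail = FALSE))
  expect_equal(chi2_pvalue(0, 0, 3, 3), 1)  # degenerate prediction margin
  expect_error(chi2_pvalue(-1, 2, 3, 4), "non-negative")
  set.seed(21)
  for (i in 1:100) {
    tb <- sample(0:12, 4, replace = TRUE)
    if ((tb[1] + tb[3]) == 0 || (tb[2] + tb[4]) == 0) next
    if ((tb[1] + tb[2]) == 0 || (tb[3] + tb[4]) == 0) {
      expect_equal(chi2_pvalue(tb[1], tb[2], tb[3], tb[4]), 1)
      next
    }
    ref <- suppressWarnings(
      chisq.test(matrix(tb, 2, byrow = TRUE), correct = FALSE))
    expect_equal(chi2_pvalue(tb[1], tb[2], tb[3], tb[4]), ref$p.value,
                 tolerance = 1e-10)
    refy <- suppressWarnings(
      chisq.test(matrix(tb, 2, byrow = TRUE), correct = TRUE))
    expect_equal(chi2_pvalue(tb[1], tb[2], tb[3], tb[4], correct = TRUE),
                 refy$p.value, tolerance = 1e-10)
  }
})

test_that("chi-squared p-value is invariant under label relabeling symmetry", {
  set.seed(22)
  for (i in 1:50) {
    tb <- sample(1:15, 4, replace = TRUE)
    p1 <- chi2_pvalue(tb[1], tb[2], tb[3], tb[4])
    # swap rows and columns simultaneously
    p2 <- chi2_pvalue(tb[4], tb[3], tb[2], tb[1])
    expect_equal(p1, p2)
  }
})

test_that("minimum p-value over thresholds matches a brute-force double loop", {
  set.seed(23)
  for (i in 1:80) {
    n <- sample(6:25, 1)
    d <- round(runif(n), 2)  # rounding forces duplicate distances
    y <- sample(c(0L, 1L), n, replace = TRUE)
    if (length(unique(y)) < 2) next
    got <- s5m:::min_pvalue_profile(d, y)
    ref <- brute_min_pvalue(d, y)
    expect_equal(got$p_min, ref$p_min, tolerance = 1e-12)
    expect_equal(got$theta, ref$theta)
  }
})

test_that("min_pvalue finds separating shapelets and handles degenerate profiles", {
  # perfectly separating: case distances all below control distances
  vals <- c(lapply(1:5, function(i) c(0, 0, runif(2, 0, 0.05))),
            lapply(1:5, function(i) c(5, 5, runif(2, 0, 0.05))))
  d <- series_dataset(vals, labels = rep(c(1, 0), each = 5))
  r <- min_pvalue(c(0, 0), d)
  expect_equal(r$p_min, chi2_pvalue(5, 0, 0, 5))
  expect_equal(unlist(r[c("a", "b", "c", "d")]), c(a = 5, b = 0, c = 0, d = 5))
  # identical distances across series: every split degenerate
  vals2 <- lapply(1:6, function(i) c(1, 1))
  d2 <- series_dataset(vals2, labels = rep(0:1, 3))
  expect_equal(min_pvalue(c(1, 1), d2)$p_min, 1)
  # toy four-series example: optimum at theta = 0.2 with table (2,0,0,2)
  d3 <- series_dataset(list(c(0, 0.1), c(0, 0.2), c(0, 0.9), c(0, 1)),
                       labels = c(1, 1, 0, 0))
  r3 <- min_pvalue(c(0, 0), d3)
  expect_equal(r3$theta, 0.2)
  expect_equal(r3$p_min, chi2_pvalue(2, 0, 0, 2))
})

test_that("Bonferroni threshold divides alpha by the number of tests", {
  expect_equal(bonferroni_threshold(0.05, 10, 5), 0.001)
  expect_equal(bonferroni_threshold(0.05, 1, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 100, 10), 1e-5)
  expect_error(bonferroni_threshold(0.05, 0, 5), "candidate")
})

test_that("Tarone threshold finds the largest feasible alpha/k", {
  tt <- tarone_threshold(c(0.001, 0.002, 0.01, 0.04, 0.2), 0.05)
  expect_equal(tt$delta, 0.05 / 3)
  expect_equal(sum(tt$testable), 3L)
  tt2 <- tarone_threshold(rep(1, 10), 0.05)
  expect_equal(tt2$delta, 0.05)
  expect_equal(sum(tt2$testable), 0L)
  tt3 <- tarone_threshold(1e-6, 0.05)
  expect_equal(tt3$delta, 0.05)
  expect_equal(sum(tt3$testable), 1L)
})

test_that("Tarone is never more conservative than Bonferroni and bounds the FWER estimate", {
  set.seed(24)
  for (i in 1:50) {
    m <- sample(5:60, 1)
    p <- 10^runif(m, -8, 0)
    alpha <- runif(1, 0.01, 0.1)
    tt <- tarone_threshold(p, alpha)
    expect_true(tt$delta * sum(tt$testable) <= alpha + 1e-12)
    # feasibility at the fixed point, per-shapelet Bonferroni comparison
    expect_true(sum(p < tt$delta) <= tt$k)
    expect_true(tt$delta >= alpha / length(p) - 1e-15)
  }
})
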