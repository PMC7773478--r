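two_item_sim <- matrix(c(1, 0.5, 0.5, 1), 2)

test_that("facility location covers its anchor cases", {
  expect_equal(facility_location(1:2, 1:2, two_item_sim), 1)
  expect_equal(facility_location(1L, 1:2, two_item_sim), 0.75)
  expect_equal(facility_location(integer(0), 1:2, two_item_sim), 0)
})

test_that("sum redundancy uses ordered pairs with the diagonal", {
  expect_equal(sum_redundancy(1:2, 1:2, two_item_sim), 0)
  expect_equal(sum_redundancy(integer(0), 1:2, two_item_sim), 3)  # 1+1+2*0.5
  expect_equal(sum_redundancy(1L, 1:2, two_item_sim), 2)
})

test_that("mixture objective reduces to its parts and honors the size-sign flag", {
  p_fl <- mixture_params(lambda_mix = 1, lambda_size = 0)
  p_sr <- mixture_params(lambda_mix = 0, lambda_size = 0)
  expect_equal(mixture_objective(1L, 1:2, p_fl, two_item_sim),
               facility_location(1L, 1:2, two_item_sim))
  expect_equal(mixture_objective(1L, 1:2, p_sr, two_item_sim),
               sum_redundancy(1L, 1:2, two_item_sim))
  # with the explicit cardinality penalty: 0.5*0.75 + 0.5*2 - 1
  p_pen <- mixture_params(size_penalty = TRUE)
  expect_equal(mixture_objective(1L, 1:2, p_pen, two_item_sim), 0.375)
  # default (sign as written): 0.5*0.75 + 0.5*2 + 1
  expect_equal(mixture_objective(1L, 1:2, mixture_params(), two_item_sim), 2.375)
})

safe_sample <- function(x, size) x[sample.int(length(x), size)]

test_that("both objectives satisfy the diminishing-returns inequality", {
  set.seed(31)
  n_checked <- 0L
  while (n_checked < 1000L) {
    k <- sample(4:8, 1)
    sm <- random_sim_matrix(k, seed = sample.int(1e6, 1))
    S <- seq_len(k)
    s <- sample(S, 1)
    Bpool <- setdiff(S, s)
    B <- sort(safe_sample(Bpool, sample(0:length(Bpool), 1)))
    R <- if (length(B)) sort(safe_sample(B, sample(0:length(B), 1))) else integer(0)
    for (f in list(facility_location, sum_redundancy)) {
      gain_R <- f(c(R, s), S, sm) - f(R, S, sm)
      gain_B <- f(c(B, s), S, sm) - f(B, S, sm)
      expect_gte(gain_R, gain_B - 1e-10)
    }
    n_checked <- n_checked + 1L
  }
})

test_that("facility location is monotone up, sum redundancy monotone down", {
  set.seed(32)
  for (i in 1:50) {
    k <- sample(4:8, 1)
    sm <- random_sim_matrix(k, seed = i)
    S <- seq_len(k)
    R <- sort(safe_sample(S, sample(1:(k - 1), 1)))
    s <- safe_sample(setdiff(S, R), 1)
    expect_gte(facility_location(c(R, s), S, sm), facility_location(R, S, sm) - 1e-12)
    expect_lte(sum_redundancy(c(R, s), S, sm), sum_redundancy(R, S, sm) + 1e-12)
  }
})

test_that("incremental caches equal scratch recomputation along random streams", {
  params <- mixture_params()
  for (run in 1:10) {
    k <- 15
    sm <- random_sim_matrix(k, seed = 100 + run)
    st <- rep_state_new(k, sm, params)
    set.seed(200 + run)
    for (i in sample(k)) {
      big_step(st, i)
      S <- st$S
      expect_equal(s5m:::state_objective(st, "R"),
                   mixture_objective(rep_state_R(st), S, params, sm),
                   tolerance = 1e-9)
      expect_equal(s5m:::state_objective(st, "B"),
                   mixture_objective(rep_state_B(st), S, params, sm),
                   tolerance = 1e-9)
      expect_true(length(intersect(rep_state_R(st), rep_state_B(st))) == 0)
      expect_setequal(c(rep_state_R(st), rep_state_B(st)), S)
    }
    # evictions must keep the caches consistent too
    for (r in rep_state_R(st)) {
      s5m:::state_evict(st, r)
      expect_equal(s5m:::state_objective(st, "R"),
                   mixture_objective(rep_state_R(st), st$S, params, sm),
                   tolerance = 1e-9)
      expect_equal(s5m:::state_objective(st, "B"),
                   mixture_objective(rep_state_B(st), st$S, params, sm),
                   tolerance = 1e-9)
    }
  }
})

test_that("first item is always representative and lazy similarity caching works", {
  vl <- lapply(1:6, function(i) sin(seq_len(5) + i))
  simf <- function(i, j) shapelet_similarity(vl[[i]], vl[[j]])
  st <- rep_state_new(6, simf, mixture_params())
  big_step(st, 3, u = 0.99)   # first item: P must be 1 regardless of draw
  expect_equal(st$last_p, 1)
  expect_equal(rep_state_R(st), 3L)
  expect_equal(s5m:::state_objective(st, "R"), mixture_objective(3L, 3L, mixture_params(),
                                                                 similarity_matrix(vl)),
               tolerance = 1e-12)
  big_step(st, 5, u = 0)      # forced accept
  expect_true(5 %in% rep_state_R(st))
  sm <- similarity_matrix(vl)
  expect_equal(st$simc[3, 5], sm[3, 5], tolerance = 1e-12)
})

test_that("a forced draw controls the stochastic assignment", {
  sm <- random_sim_matrix(8, seed = 41)
  st <- rep_state_new(8, sm, mixture_params())
  for (i in 1:4) big_step(st, i, u = 0)    # all accepted
  expect_equal(sort(rep_state_R(st)), 1:4)
  big_step(st, 5, u = 0.9999999)           # rejected unless P == 1
  expect_true(!(5 %in% rep_state_R(st)) || st$last_p == 1)
})
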