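test_that("exhaustive search handles duplicates and near-noiseless prototypes", {
  params <- mixture_params()
  # duplicated items: exactly one per duplicate group
  vl <- list(c(0, 5), c(0, 5), c(5, 0), c(5, 0), c(2, 2))
  sm <- similarity_matrix(vl)
  best <- exhaustive_select(1:5, params, sm)
  expect_equal(sum(best %in% 1:2), 1L)
  expect_equal(sum(best %in% 3:4), 1L)
  # five nearly noiseless prototypes: all five selected
  spec <- simulation_spec(n_per_prototype = 2, sigma = 0.01, seed = 5)
  reps <- generate_replicates(spec)
  sm2 <- similarity_matrix(reps$sequences)
  best2 <- exhaustive_select(1:10, params, sm2)
  expect_equal(sort(unique(reps$prototype[best2])), 1:5)
  expect_equal(length(best2), 5L)
  expect_error(exhaustive_select(1:20, params, sm2), "14")
})

test_that("greedy selects one item per identical group and all dissimilar items", {
  params <- mixture_params()
  sm_same <- matrix(1, 4, 4)
  expect_equal(length(greedy_select(1:4, params, sm_same)), 1L)
  sm_diff <- matrix(0.001, 5, 5); diag(sm_diff) <- 1
  expect_equal(sort(greedy_select(1:5, params, sm_diff)), 1:5)
})

test_that("greedy is near-optimal against the exhaustive oracle on random instances", {
  params <- mixture_params()
  ok <- 0L
  for (i in 1:40) {
    k <- sample(5:9, 1)
    sm <- random_sim_matrix(k, seed = 500 + i)
    opt <- exhaustive_select(seq_len(k), params, sm)
    o_opt <- mixture_objective(opt, seq_len(k), params, sm)
    o_gre <- mixture_objective(greedy_select(seq_len(k), params, sm),
                               seq_len(k), params, sm)
    expect_lte(o_gre, o_opt + 1e-9)   # oracle bounds greedy
    if (o_gre >= 0.5 * o_opt - 1e-9) ok <- ok + 1L
  }
  expect_gte(ok / 40, 0.95)
})

test_that("bidirectional greedy is seed-reproducible and respects forced gains", {
  params <- mixture_params()
  sm <- random_sim_matrix(12, seed = 51)
  r1 <- bidirectional_greedy_select(1:12, params, sm, seed = 7)
  r2 <- bidirectional_greedy_select(1:12, params, sm, seed = 7)
  expect_identical(r1, r2)
  r3 <- bidirectional_greedy_select(1:12, params, sm, seed = 8)
  expect_true(all(r3 %in% 1:12))
})

test_that("streaming selection is seed-reproducible and partitions the stream", {
  params <- mixture_params()
  sm <- random_sim_matrix(30, seed = 52)
  r1 <- big_select(1:30, params, sm, seed = 3)
  r2 <- big_select(1:30, params, sm, seed = 3)
  expect_identical(r1, r2)
  st <- rep_state_new(30, sm, params)
  with_seed <- s5m:::with_seed
  with_seed(3, for (i in 1:30) big_step(st, i))
  expect_setequal(c(rep_state_R(st), rep_state_B(st)), 1:30)
  expect_identical(sort(r1), sort(rep_state_R(st)))
})

test_that("streaming work per item is linear in the processed prefix", {
  params <- mixture_params()
  sm <- random_sim_matrix(60, seed = 53)
  st <- rep_state_new(60, sm, params)
  evals <- integer(60)
  set.seed(1)
  for (i in 1:60) {
    before <- st$sim_evals
    big_step(st, i)
    evals[i] <- st$sim_evals - before
  }
  # exactly the processed-prefix length per step, O(n) total per item
  expect_equal(evals, 0:59)
})

test_that("threshold selection degenerates correctly at extreme cutoffs", {
  vl <- list(c(0, 1), c(0, 1), c(5, 0), c(9, 9))
  sm <- similarity_matrix(vl)
  # tau near 1: every structurally distinct item selected, duplicate dropped
  expect_equal(threshold_select(1:4, 0.999, sm), c(1L, 3L, 4L))
  # tau near 0: only the first item
  expect_equal(threshold_select(1:4, 1e-6, sm), 1L)
  expect_error(threshold_select(1:4, 1.5, sm), "tau")
})

test_that("all optimizers recover high-fidelity sets on low-noise replicate data", {
  spec <- simulation_spec(n_per_prototype = 8, sigma = 0.1, seed = 6)
  reps <- generate_replicates(spec)
  sm <- similarity_matrix(reps$sequences)
  protos <- make_prototype_set()
  params <- mixture_params()
  S <- seq_along(reps$sequences)
  sels <- list(greedy = greedy_select(S, params, sm),
               bidir = bidirectional_greedy_select(S, params, sm, seed = 1),
               big = big_select(S, params, sm, seed = 1),
               thresh = threshold_select(S, 0.5, sm))
  for (nm in names(sels)) {
    sel <- sels[[nm]]
    expect_gte(min_sim(reps$sequences[sel], protos), 0.7)
  }
  # the optimizers agree to within noise on the objective (single pass vs greedy)
  objs <- vapply(sels, function(sel) mixture_objective(sel, S, params, sm), numeric(1))
  expect_lte(max(objs) - min(objs), 0.05 * max(abs(objs)))
})
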