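test_that("simulated tables follow the long-format schema", {
  sim <- simulate_responses("2_component", kappa = 15, p_u = 0.25,
                            n_trials = 50, set_size = 4, seed = 1)
  expect_named(sim, c("id", "set_size", "target", "response",
                      "non_target_1", "non_target_2", "non_target_3"))
  expect_equal(nrow(sim), 50)
  expect_true(all(sim$id == 1))
  expect_true(all(abs(sim$response) <= pi & abs(sim$target) <= pi))
  # set size 1 emits no non-target columns
  s1 <- simulate_responses("2_component", kappa = 8, p_u = 0.1,
                           n_trials = 10, set_size = 1, seed = 2)
  expect_named(s1, c("id", "set_size", "target", "response"))
  # stimulus values lie on the integer-degree grid
  degs <- sim$target * 180 / pi
  expect_equal(degs, round(degs), tolerance = 1e-9)
})

test_that("simulation is reproducible under a fixed seed and leaves the RNG alone", {
  a <- simulate_responses("3_component", kappa = 6, p_u = 0.1, p_n = 0.1,
                          n_trials = 40, set_size = 4, seed = 123)
  b <- simulate_responses("3_component", kappa = 6, p_u = 0.1, p_n = 0.1,
                          n_trials = 40, set_size = 4, seed = 123)
  expect_identical(a, b)
  d <- simulate_responses("3_component", kappa = 6, p_u = 0.1, p_n = 0.1,
                          n_trials = 40, set_size = 4, seed = 124)
  expect_false(identical(a$response, d$response))
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(simulate_responses("2_component", kappa = 8, p_u = 0.1,
                                             n_trials = 10, seed = 5))
  expect_identical(runif(1), before)
})

test_that("separation policies shape the stimulus display", {
  # fixed separation: consecutive 5-degree spacing regardless of probe position
  st <- generate_stimuli(200, set_size = 4,
                         separation_policy = "fixed_separation",
                         separation = 5, seed = 11)
  for (i in c(1, 57, 200)) {
    deg <- sort(round(as.numeric(st[i, ]) * 180 / pi) %% 360)
    gaps <- sort(diff(c(deg, deg[1] + 360)))
    expect_equal(gaps, c(5, 5, 5, 345))
  }
  # minimum separation: every pairwise circular distance respects the floor
  st <- generate_stimuli(300, set_size = 8,
                         separation_policy = "min_separation",
                         separation = 40, seed = 12)
  m <- as.matrix(st)
  for (i in seq_len(nrow(m))) {
    d <- abs(outer(m[i, ], m[i, ], function(a, b) wrap_angle(a - b)))
    expect_gte(min(d[upper.tri(d)]) * 180 / pi, 40 - 1e-9)
  }
  expect_error(generate_stimuli(5, 8, "fixed_separation", separation = 50),
               "infeasible")
  expect_error(generate_stimuli(5, 4, "min_separation"), "separation")
})

test_that("pure guessing produces uniform response errors", {
  sim <- simulate_responses("2_component", kappa = 8, p_u = 1,
                            n_trials = 1e5, set_size = 4, seed = 21)
  err <- response_error(sim$response, sim$target)
  expect_lt(circular_moments(err)$R, 0.01)
})

test_that("multiple set sizes are allocated evenly and parameters recycled per size", {
  sim <- simulate_responses("2_component", kappa = c(8, 8, 8, 8),
                            p_u = c(0.1, 0.2, 0.3, 0.4), n_trials = 203,
                            set_size = c(1, 2, 4, 6), seed = 31)
  counts <- table(sim$set_size)
  expect_true(max(counts) - min(counts) <= 1)
  expect_equal(sum(counts), 203)
  expect_named(sim, c("id", "set_size", "target", "response",
                      paste0("non_target_", 1:5)))
  expect_true(all(is.na(sim$non_target_1[sim$set_size == 1])))
  expect_true(all(!is.na(sim$non_target_3[sim$set_size == 6])))
  expect_error(simulate_responses("2_component", kappa = c(8, 9), p_u = 0.1,
                                  n_trials = 10, set_size = c(1, 2, 4)),
               "matching|length")
})

test_that("simulated mixture weights are consistent with the generating model", {
  # moderate-n check; the full 1e5-trial weight consistency runs in the
  # acceptance suite
  sim <- simulate_responses("3_component", kappa = 12, p_u = 0.1, p_n = 0.3,
                            n_trials = 20000, set_size = 4,
                            separation_policy = "min_separation",
                            separation = 40, seed = 41)
  f <- fit_mixture_model(sim, "3_component", unit = "radians")
  expect_lt(abs(f$p_t - 0.6), 0.025)
  expect_lt(abs(f$p_n - 0.3), 0.025)
  expect_lt(abs(f$p_u - 0.1), 0.025)
})

test_that("slots-model simulation respects capacity across set sizes", {
  # K = 2, set size 4: half the trials should be guesses
  sim <- simulate_responses("slots", kappa = 20, K = 2, n_trials = 4000,
                            set_size = 4, seed = 51)
  err <- response_error(sim$response, sim$target)
  # fraction of large errors approximates the implied guess rate 0.5
  p_far <- mean(abs(err) > pi / 2)   # guesses land there w.p. 1/2
  expect_lt(abs(p_far - 0.25), 0.03)
  # K >= set size: no guessing, tight errors
  sim2 <- simulate_responses("slots", kappa = 20, K = 4, n_trials = 2000,
                             set_size = 2, seed = 52)
  err2 <- response_error(sim2$response, sim2$target)
  expect_gt(circular_moments(err2)$R, 0.95)
})
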