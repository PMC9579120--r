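test_that("two-component density matches its definition", {
  # pure guessing: uniform density regardless of error
  expect_equal(density_two_component(1.7, kappa = 8, p_u = 1), 1 / (2 * pi))
  # kappa = 0: von Mises collapses to uniform
  expect_equal(density_two_component(0, kappa = 0, p_u = 0), 1 / (2 * pi))
  # frozen via the Bessel oracle: 0.8 * e^8 / (2 pi I0(8)) + 0.2 / (2 pi)
  expect_equal(density_two_component(0, kappa = 8, p_u = 0.2),
               0.8 * vm_density_oracle(0, 0, 8) + 0.2 / (2 * pi),
               tolerance = 1e-10)
  expect_equal(density_two_component(0, kappa = 8, p_u = 0.2), 0.919530,
               tolerance = 1e-5)
  expect_error(density_two_component(0, kappa = 8, p_u = 1.2), "probabilities")
})

test_that("three-component density adds the swap term and reduces at p_n = 0", {
  nts <- c(0.1, -2.0, 1.4)
  # reduction: p_n = 0 is pointwise the two-component model
  for (e in seq(-3, 3, by = 0.5)) {
    expect_equal(density_three_component(e, 8, 0.2, 0, nts),
                 density_two_component(e, 8, 0.2), tolerance = 1e-12)
  }
  # pure swap with one non-target at deviation zero: von Mises peak height
  expect_equal(density_three_component(2.2, 8, 0, 1, nontarget_errors = 0),
               vm_density_oracle(0, 0, 8), tolerance = 1e-10)
  expect_equal(density_three_component(2.2, 8, 0, 1, nontarget_errors = 0),
               1.109620, tolerance = 1e-5)
  # invariant under permutation of the non-target errors
  expect_equal(density_three_component(0.6, 5, 0.1, 0.3, nts),
               density_three_component(0.6, 5, 0.1, 0.3, rev(nts)),
               tolerance = 1e-14)
  expect_error(density_three_component(0, 8, 0.1, 0.2), "non-target")
})

test_that("all four densities integrate to one over the circle", {
  set.seed(21)
  target <- 0.8
  nts <- c(-2.1, 0.3, 2.9)
  for (rep in 1:5) {
    kappa <- runif(1, 0.5, 50)
    p_u <- runif(1, 0, 0.5)
    p_n <- runif(1, 0, 0.5)
    K <- runif(1, 0.5, 10)
    ss <- sample(c(1, 2, 4, 6), 1)
    f2 <- function(x) vapply(x, function(xi)
      density_two_component(wrap_angle(xi - target), kappa, p_u), numeric(1))
    f3 <- function(x) vapply(x, function(xi)
      density_three_component(wrap_angle(xi - target), kappa, p_u, p_n,
                              wrap_angle(xi - nts)), numeric(1))
    fs <- function(x) vapply(x, function(xi)
      slots_density(wrap_angle(xi - target), K, kappa, ss), numeric(1))
    fa <- function(x) vapply(x, function(xi)
      spa_density(wrap_angle(xi - target), K, kappa, ss), numeric(1))
    expect_equal(circle_integral(f2), 1, tolerance = 1e-6)
    expect_equal(circle_integral(f3), 1, tolerance = 1e-6)
    expect_equal(circle_integral(fs), 1, tolerance = 1e-6)
    expect_equal(circle_integral(fa), 1, tolerance = 1e-6)
  }
})

test_that("slots model re-parameterises the guess rate through capacity", {
  # capacity not exceeded: pure von Mises
  expect_equal(slots_density(0.4, K = 5, kappa = 8, set_size = 4),
               dvonmises(0.4, 0, 8), tolerance = 1e-12)
  # K = 2 of 4 items stored: implied p_u = 0.5
  expect_equal(slots_density(0.4, K = 2, kappa = 8, set_size = 4),
               0.5 * dvonmises(0.4, 0, 8) + 0.5 / (2 * pi), tolerance = 1e-12)
  # K = 3: storage probability 1 at set size 3 vs 0.5 at set size 6
  p_t_at <- function(ss) min(1, 3 / ss)
  expect_equal(p_t_at(3) / p_t_at(6), 2)
})

test_that("slots-plus-averaging sharpens representations with spare slots", {
  # K = set_size: one slot per item, identical to the slots model
  expect_equal(spa_density(0.3, K = 4, kappa = 8, set_size = 4),
               slots_density(0.3, K = 4, kappa = 8, set_size = 4),
               tolerance = 1e-12)
  # K = 8, set size 4: every item in two slots, sd shrunk by sqrt(2)
  k2 <- sd_to_kappa(kappa_to_sd(8) / sqrt(2))
  expect_equal(spa_density(0.3, K = 8, kappa = 8, set_size = 4),
               dvonmises(0.3, 0, k2), tolerance = 1e-8)
  # averaging raises the central peak whenever K > set_size
  expect_gt(spa_density(0, K = 6, kappa = 8, set_size = 4),
            slots_density(0, K = 6, kappa = 8, set_size = 4))
  # continuous in K across the capacity boundary
  eps <- 1e-7
  expect_equal(spa_density(0.2, K = 4 - eps, kappa = 8, set_size = 4),
               spa_density(0.2, K = 4 + eps, kappa = 8, set_size = 4),
               tolerance = 1e-5)
})

test_that("negative log-likelihood agrees between R densities and the compiled kernel", {
  expect_equal(negative_log_likelihood(tiny_trials(0.3, 1.2), "2_component",
                                       kappa = 8, p_u = 1),
               -log(1 / (2 * pi)), tolerance = 1e-12)
  set.seed(33)
  sim <- simulate_responses("3_component", kappa = 6, p_u = 0.15, p_n = 0.2,
                            n_trials = 200, set_size = 4)
  err <- response_error(sim$response, sim$target)
  nte <- wrap_angle(sim$response - as.matrix(sim[paste0("non_target_", 1:3)]))
  for (par in list(c(6, 0.15, 0.2), c(2, 0.4, 0.05), c(30, 0.01, 0.3))) {
    ref <- -sum(log(vapply(seq_len(200), function(i)
      density_three_component(err[i], par[1], par[2], par[3], nte[i, ]),
      numeric(1))))
    expect_equal(negative_log_likelihood(sim, "3_component", kappa = par[1],
                                         p_u = par[2], p_n = par[3]),
                 ref, tolerance = 1e-8)
  }
  # two- vs three-component equivalence at p_n = 0, and kappa discrimination
  expect_equal(negative_log_likelihood(sim, "2_component", kappa = 5, p_u = 0.2),
               negative_log_likelihood(sim, "3_component", kappa = 5, p_u = 0.2,
                                       p_n = 0), tolerance = 1e-10)
  sim8 <- simulate_responses("2_component", kappa = 8, p_u = 0, n_trials = 1000,
                             set_size = 4, seed = 2)
  expect_lt(negative_log_likelihood(sim8, "2_component", kappa = 8, p_u = 0.01),
            negative_log_likelihood(sim8, "2_component", kappa = 2, p_u = 0.01))
  # slots kernel agrees with the R slots densities
  err8 <- response_error(sim8$response, sim8$target)
  for (K in c(1.5, 4, 6.3)) {
    ref <- -sum(log(vapply(err8, function(e) spa_density(e, K, 8, 4), numeric(1))))
    expect_equal(negative_log_likelihood(sim8, "slots_averaging", kappa = 8, K = K),
                 ref, tolerance = 1e-6)
    ref_s <- -sum(log(vapply(err8, function(e) slots_density(e, K, 8, 4), numeric(1))))
    expect_equal(negative_log_likelihood(sim8, "slots", kappa = 8, K = K),
                 ref_s, tolerance = 1e-6)
  }
  # out-of-bound proposals yield +Inf rather than an error
  expect_identical(negative_log_likelihood(sim, "3_component", kappa = 5,
                                           p_u = 0.7, p_n = 0.5), Inf)
})
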