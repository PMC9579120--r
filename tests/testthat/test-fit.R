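test_that("start grid enumerates the documented permutations", {
  g2 <- start_grid("2_component")
  expect_equal(nrow(g2), 9)
  expect_setequal(unique(g2$kappa), c(1, 10, 100))
  expect_setequal(unique(g2$p_u), c(0.01, 0.1, 0.4))
  g3 <- start_grid("3_component")
  expect_equal(nrow(g3), 27)
  expect_true(any(g3$kappa == 10 & g3$p_u == 0.4 & g3$p_n == 0.01))
  expect_true(all(g3$p_u + g3$p_n <= 1))
  gs <- start_grid("slots")
  expect_equal(nrow(gs), 9)
  expect_setequal(unique(gs$K), c(1, 2, 4))
})

test_that("information criteria follow their definitions exactly", {
  ic <- information_criteria(-100, n_params = 2, n_trials = 100)
  expect_equal(ic$AIC, 204)
  expect_equal(ic$AICc, 200 + 4 * (100 / 97))   # 204.12371...
  expect_equal(ic$AICc, 204.12371, tolerance = 1e-5)
  expect_equal(ic$BIC, 200 + 2 * log(100))      # 209.21034...
  expect_equal(ic$BIC, 209.21034, tolerance = 1e-5)
  expect_true(is.na(information_criteria(-10, 3, 4)$AICc))
  # AICc >= AIC whenever defined
  ic2 <- information_criteria(-50, 3, 30)
  expect_gte(ic2$AICc, ic2$AIC)
})

test_that("model comparison uses the two-minus-three orientation and the -2 bound", {
  mk <- function(ll, p, n) {
    ic <- information_criteria(ll, p, n)
    data.frame(id = 1, kappa = 5, p_t = 0.9, p_u = 0.1,
               log_likelihood = ll, n_trials = n, AIC = ic$AIC,
               AICc = ic$AICc, BIC = ic$BIC)
  }
  # identical log-likelihoods: AIC difference is exactly -2
  cmp <- compare_models(mk(-500, 2, 500), mk(-500, 3, 500))
  expect_equal(cmp$AIC_difference, -2)
  expect_equal(cmp$BIC_difference, -log(500))
  expect_equal(cmp$BIC_difference, -6.2146, tolerance = 1e-4)
  expect_equal(cmp$AIC_winner, "2_component")
  expect_false(cmp$bound_violated)
  # a 10-unit log-likelihood advantage: 1004 - 986 = 18
  cmp <- compare_models(mk(-500, 2, 500), mk(-490, 3, 500))
  expect_equal(cmp$AIC_difference, 18)
  expect_equal(cmp$AIC_winner, "3_component")
  # sub-bound differences are flagged as optimiser failures
  expect_warning(cmp <- compare_models(mk(-500, 2, 500), mk(-501, 3, 500)),
                 "bound")
  expect_true(cmp$bound_violated)
  expect_error(compare_models(mk(-500, 2, 500), mk(-500, 3, 400)), "different")
})

test_that("fitting recovers generating parameters at large n", {
  sim <- simulate_responses("2_component", kappa = 8, p_u = 0.1,
                            n_trials = 1000, set_size = 4, seed = 61)
  f <- fit_mixture_model(sim, "2_component", unit = "radians")
  expect_gt(f$kappa, 6.5); expect_lt(f$kappa, 9.5)
  expect_gt(f$p_u, 0.06); expect_lt(f$p_u, 0.14)
  expect_equal(f$p_t + f$p_u, 1, tolerance = 1e-9)
  # pure guessing data must be attributed to the uniform component
  unif <- simulate_responses("2_component", kappa = 5, p_u = 1,
                             n_trials = 10000, set_size = 4, seed = 62)
  f <- fit_mixture_model(unif, "2_component", unit = "radians")
  expect_gte(f$p_u, 0.95)
  # three-component weights at large n
  sim3 <- simulate_responses("3_component", kappa = 8, p_u = 0.1, p_n = 0.25,
                             n_trials = 5000, set_size = 4, seed = 63)
  f3 <- fit_mixture_model(sim3, "3_component", unit = "radians")
  expect_lt(abs(f3$p_n - 0.25), 0.03)
  expect_equal(f3$p_t + f3$p_u + f3$p_n, 1, tolerance = 1e-9)
})

test_that("multi-start dominance and two/three-component nesting hold", {
  set.seed(71)
  for (rep in 1:3) {
    gen_pn <- c(0, 0.15, 0.08)[rep]
    sim <- simulate_responses("3_component", kappa = runif(1, 2, 12),
                              p_u = runif(1, 0, 0.3), p_n = gen_pn,
                              n_trials = 300, set_size = 4)
    f2 <- fit_mixture_model(sim, "2_component", unit = "radians", return_fit = TRUE)
    f3 <- fit_mixture_model(sim, "3_component", unit = "radians", return_fit = TRUE)
    # nesting: the richer model never fits worse
    expect_gte(f3$log_likelihood, f2$log_likelihood - 1e-6)
    # dominance: the returned optimum beats every grid start
    g <- start_grid("2_component")
    starts <- vapply(seq_len(nrow(g)), function(i)
      negative_log_likelihood(sim, "2_component", kappa = g$kappa[i],
                              p_u = g$p_u[i]), numeric(1))
    expect_lte(-f2$log_likelihood, min(starts) + 1e-9)
    # probabilities are a simplex
    expect_true(all(c(f3$p_t, f3$p_u, f3$p_n) >= 0))
    expect_equal(f3$p_t + f3$p_u + f3$p_n, 1, tolerance = 1e-9)
  }
})

test_that("fits are produced per grouping cell with sensible edge handling", {
  set.seed(81)
  dat <- do.call(rbind, lapply(1:2, function(p) {
    d <- simulate_responses("3_component", kappa = 8, p_u = 0.1,
                            p_n = c(0, 0.1), n_trials = 240,
                            set_size = c(1, 4))
    d$id <- p
    d
  }))
  f <- fit_mixture_model(dat, "3_component", unit = "radians",
                         set_size_var = "set_size", return_fit = TRUE)
  expect_equal(nrow(f), 4)
  # set-size-1 cells carry no non-targets: p_n fixed at zero
  expect_true(all(f$p_n[f$set_size == 1] == 0))
  expect_true(all(f$p_n[f$set_size == 4] >= 0))
  expect_named(f, c("id", "set_size", "kappa", "p_t", "p_n", "p_u",
                    "log_likelihood", "n_trials", "AIC", "AICc", "BIC"))
  expect_error(fit_mixture_model(dat, "3_component", unit = "radians",
                                 set_size_var = "wrong"), "not found")
  # a cell with fewer than two trials is skipped with a warning
  small <- dat[c(1, which(dat$id == 2)), ]
  small$id[1] <- 99
  expect_warning(fit_mixture_model(small, "3_component", unit = "radians",
                                   set_size_var = "set_size"), "skipped")
})

test_that("slots and slots-plus-averaging fits recover capacity across set sizes", {
  sim <- simulate_responses("slots", kappa = 10, K = 2.5,
                            n_trials = 3000, set_size = c(2, 4, 6), seed = 91)
  f <- fit_mixture_model(sim, "slots", unit = "radians", return_fit = TRUE)
  expect_equal(f$K, 2.5, tolerance = 0.35)
  expect_equal(f$kappa, 10, tolerance = 1.5)
  sim2 <- simulate_responses("slots_averaging", kappa = 10, K = 5,
                             n_trials = 3000, set_size = c(2, 4, 6), seed = 92)
  fa <- fit_mixture_model(sim2, "slots_averaging", unit = "radians")
  expect_equal(fa$K, 5, tolerance = 0.8)
  expect_named(fa, c("id", "K", "kappa"))
})
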