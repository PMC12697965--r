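test_that("raw-scale transforms behave and invert", {
  expect_equal(to_natural(0, "unit"), 0.5)
  expect_equal(to_natural(0, "positive"), 1)
  x <- seq(-10, 10, length.out = 101)
  expect_true(all(diff(to_natural(x, "unit")) > 0))
  expect_equal(to_raw(to_natural(x, "unit"), "unit"), x,
               tolerance = 1e-9)
  expect_equal(to_raw(to_natural(x, "positive"), "positive"), x,
               tolerance = 1e-12)
})

test_that("WAIC matches its defining formula", {
  # degenerate posterior: identical draws, no effective parameters
  ll <- matrix(rep(c(-1.2, -0.4), each = 3), nrow = 3)
  w0 <- waic(ll)
  expect_equal(w0$p_waic, 0)
  expect_equal(w0$waic, -2 * sum(ll[1, ]))

  # hand-computed 3 draws x 2 trials
  ll <- matrix(c(-1.0, -2.0, -1.5,
                 -0.3, -0.6, -0.2), nrow = 3)
  lppd <- log(mean(exp(ll[, 1]))) + log(mean(exp(ll[, 2])))
  p <- var(ll[, 1]) + var(ll[, 2])
  w <- waic(ll)
  expect_equal(w$lppd, lppd, tolerance = 1e-12)
  expect_equal(w$p_waic, p, tolerance = 1e-12)
  expect_equal(w$waic, -2 * (lppd - p), tolerance = 1e-12)

  # invariant to trial order; errors on one draw
  expect_equal(waic(ll[, 2:1])$waic, w$waic)
  expect_error(waic(ll[1, , drop = FALSE]), "2 posterior draws")

  set.seed(23)
  for (i in 1:20) {
    m <- matrix(rnorm(60, -1, 0.5), nrow = 6)
    wi <- waic(m)
    expect_gte(wi$p_waic, 0)
    expect_equal(wi$waic, -2 * (wi$lppd - wi$p_waic), tolerance = 1e-12)
  }
})

test_that("log joint matches a hand-assembled oracle", {
  sim <- generate_study(small_design(1L, 1L), "full", seed = 44L)
  study <- sim$study[sim$study$phase == "observational", ][1:3, ]
  theta <- matrix(c(0.2, -0.4, 0.8, 1.1), 1)
  mu <- c(0.1, 0, -0.2, 0.5)
  sigma <- c(1, 0.8, 1.2, 2)

  nat <- c(plogis(theta[1:3]), exp(theta[4]))
  ll <- sequence_loglik(learner_params(nat[1], nat[2], nat[3], nat[4]),
                        study, "full")$total
  pop <- sum(dnorm(theta[1, ], mu, sigma, log = TRUE))
  hyper <- sum(dnorm(mu, 0, 1, log = TRUE)) +
    sum(log(2) + dcauchy(sigma, 0, 3, log = TRUE))
  expect_equal(log_joint(study, "full", theta, mu, sigma),
               ll + pop + hyper, tolerance = 1e-10)

  expect_error(log_joint(study, "full", theta, mu[1:2], sigma[1:2]))
  expect_error(log_joint(study, "full", rbind(theta, theta), mu, sigma),
               "participants")
})

test_that("split R-hat separates converged from diverged chains", {
  set.seed(24)
  same <- cbind(rnorm(400), rnorm(400))
  expect_lt(split_rhat(same), 1.05)
  apart <- cbind(rnorm(400), rnorm(400) + 5)
  expect_gt(split_rhat(apart), 1.5)
})

test_that("the hierarchical sampler recovers parameters and is seeded", {
  sim <- cached_small_study()
  fit <- cached_small_fit()
  expect_s3_class(fit, "oblearn_fit")
  pm <- fit$posterior_means
  expect_true(all(pm$alpha_v >= 0 & pm$alpha_v <= 1))
  expect_true(all(pm$w_a >= 0 & pm$w_a <= 1))
  expect_true(all(pm$beta > 0))
  m <- merge(sim$truth, pm, by = "participant_id",
             suffixes = c("_t", "_e"))
  expect_gt(cor(m$w_a_t, m$w_a_e), 0)
  expect_gt(cor(m$alpha_a_t, m$alpha_a_e), 0)
  # WAIC internals consistent
  expect_gte(fit$waic$p_waic, 0)
  expect_equal(fit$waic$waic, -2 * (fit$waic$lppd - fit$waic$p_waic),
               tolerance = 1e-9)
  expect_equal(ncol(fit$pointwise),
               sum(sim$study$phase == "observational"))
  # diagnostics cover every scalar parameter
  expect_equal(nrow(fit$diagnostics), dim(fit$draws)[3])
  expect_true(all(is.finite(fit$diagnostics$rhat)))

  refit <- fit_hierarchical(sim$study, "full", chains = 2L, warmup = 150L,
                            iter = 150L, seed = 7L)
  expect_identical(refit$draws, fit$draws)
})

test_that("partial models drop the unused parameters", {
  sim <- cached_small_study()
  f_act <- fit_hierarchical(sim$study, "action_only", chains = 2L,
                            warmup = 100L, iter = 100L, seed = 3L)
  expect_named(f_act$posterior_means,
               c("participant_id", "alpha_a", "beta"))
  f_rew <- fit_hierarchical(sim$study, "reward_only", chains = 2L,
                            warmup = 100L, iter = 100L, seed = 3L)
  expect_named(f_rew$posterior_means,
               c("participant_id", "alpha_v", "beta"))
  tab <- compare_waic(list(cached_small_fit(), f_act, f_rew))
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$waic, sort(tab$waic))
})
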