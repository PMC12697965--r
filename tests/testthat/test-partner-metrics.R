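test_that("performance is the total passive-phase reward", {
  expect_identical(performance(c(1, 0, 1, 1)), 3L)
  expect_identical(performance(rep(0, 30)), 0L)
  expect_identical(performance(rep(1, 30)), 30L)
  expect_error(performance(c(1, 2)))
})

test_that("predictability matches a hand-stepped information-bonus oracle", {
  p <- info_bonus_params(alpha = 0.3, beta = 2, kappa = 0.6)
  choices <- c(0L, 0L, 2L)
  rewards <- c(1L, 0L, 1L)
  q <- c(0.5, 0.5, 0.5); n <- c(1, 1, 1)
  ll <- 0
  for (t in 1:3) {
    val <- q + 0.6 / n
    pr <- exp(2 * val) / sum(exp(2 * val))
    ll <- ll + log(pr[choices[t] + 1])
    q[choices[t] + 1] <- q[choices[t] + 1] +
      0.3 * (rewards[t] - q[choices[t] + 1])
    n[choices[t] + 1] <- n[choices[t] + 1] + 1
  }
  expect_equal(predictability(p, choices, rewards), ll,
               tolerance = 1e-12)

  # uniform policy at beta = 0; log-probabilities are never positive
  p0 <- info_bonus_params(0.3, 0, 0.2)
  expect_equal(predictability(p0, rep(0L, 30), rep(1L, 30)),
               30 * log(1 / 3), tolerance = 1e-12)
  set.seed(25)
  expect_lte(predictability(p, sample(0:2, 20, TRUE),
                            sample(0:1, 20, TRUE)), 0)
})

test_that("the practice-phase fit returns in-support parameters", {
  sim <- cached_small_study()
  fit <- fit_practice_model(sim$study, chains = 2L, warmup = 100L,
                            iter = 100L, seed = 5L)
  pm <- fit$posterior_means
  expect_named(pm, c("participant_id", "alpha", "beta", "kappa"))
  expect_true(all(pm$alpha >= 0 & pm$alpha <= 1))
  expect_true(all(pm$kappa >= 0 & pm$kappa <= 1))
  expect_true(all(pm$beta > 0))
})

test_that("partner metrics order the noise conditions as designed", {
  # low-noise partners earn more; high-noise partners induce more
  # information gain at matched kappa
  set.seed(26)
  perf <- list(high = numeric(0), low = numeric(0))
  gain <- list(high = numeric(0), low = numeric(0))
  for (r in 1:100) {
    for (cond in c("high", "low")) {
      pt <- simulate_partner(partner_preset(paste0(cond, "_noise")),
                             n_trials = 30)
      perf[[cond]] <- c(perf[[cond]], sum(pt$reward))
      gain[[cond]] <- c(gain[[cond]], information_gain(pt$choice, 0.5))
    }
  }
  expect_gt(mean(perf$low), mean(perf$high))
  expect_gt(mean(gain$high), mean(gain$low))
})

test_that("metric rows cover both sides and stay in range", {
  sim <- cached_small_study()
  pf <- fit_practice_model(sim$study, chains = 2L, warmup = 80L,
                           iter = 80L, seed = 2L)
  m <- partner_metrics(sim$study, pf)
  n_blocks <- nrow(unique(sim$study[sim$study$phase == "observational",
                                    c("participant_id", "block_id")]))
  expect_equal(nrow(m), 2L * n_blocks)
  expect_true(all(m$performance >= 0 & m$performance <= 30))
  expect_true(all(m$predictability <= 0))
  expect_true(all(m$information_gain >= 0))
  expect_setequal(unique(m$side), c("left", "right"))
})

test_that("selection regressors difference, standardise and antisymmetrise", {
  base <- tidyr::expand_grid(participant_id = 1:6, block_id = 1:4)
  set.seed(27)
  metrics <- dplyr::bind_rows(
    dplyr::mutate(base, side = "left", noise = "high",
                  performance = rpois(nrow(base), 12),
                  predictability = -runif(nrow(base), 10, 40),
                  information_gain = runif(nrow(base), 0.5, 1.5)),
    dplyr::mutate(base, side = "right", noise = "low",
                  performance = rpois(nrow(base), 18),
                  predictability = -runif(nrow(base), 5, 20),
                  information_gain = runif(nrow(base), 0.2, 1.0)))
  reg <- selection_regressors(metrics)
  for (v in c("z_performance", "z_predictability", "z_information_gain")) {
    expect_equal(mean(reg[[v]]), 0, tolerance = 1e-10)
    expect_equal(sd(reg[[v]]), 1, tolerance = 1e-10)
  }
  # swapping sides flips every raw difference
  swapped <- metrics
  swapped$side <- ifelse(metrics$side == "left", "right", "left")
  reg2 <- selection_regressors(swapped)
  expect_equal(reg2$d_performance, -reg$d_performance)
  expect_equal(reg2$d_predictability, -reg$d_predictability)

  # identical sides give zero differences, and zero variance errors
  same <- metrics
  same$performance <- 10
  same$predictability <- -20
  same$information_gain <- 1
  expect_error(selection_regressors(same), "performance")
})
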