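test_that("selection designs encode the stated coding scheme", {
  study <- dplyr::bind_rows(
    selection_block(1L, 1L, left_noise = "high", left_first = TRUE,
                    selected = "high"),
    selection_block(1L, 2L, left_noise = "low", left_first = FALSE,
                    selected = "high"),
    selection_block(2L, 1L, left_noise = "low", left_first = FALSE,
                    selected = "low"))
  d <- build_selection_design(study, "model2")
  r11 <- d[d$participant_id == 1 & d$block_id == 1, ]
  expect_equal(r11$Y, 1L)    # high on left, high chosen -> left chosen
  expect_equal(r11$X1, 1)    # high-noise partner on the left
  expect_equal(r11$X2, 1)    # left partner shown first
  r12 <- d[d$participant_id == 1 & d$block_id == 2, ]
  expect_equal(r12$Y, 0L)    # low on left but high chosen
  expect_equal(r12$X1, -1)
  expect_equal(r12$X2, -1)
  r21 <- d[d$participant_id == 2 & d$block_id == 1, ]
  expect_equal(r21$Y, 1L)    # low on left, low chosen
  expect_equal(r21$X1, -1)

  d1 <- build_selection_design(study, "model1")
  expect_named(d1, c("participant_id", "block_id", "Y", "X1"))
  expect_equal(nrow(d1), 3L)
})

test_that("pooled effects use inverse-variance weights", {
  p <- pool_effects(c(1.0, 2.0), c(0.1, 0.2))
  expect_equal(p$estimate, 1.2, tolerance = 1e-12)
  expect_equal(p$se, sqrt(1 / 125), tolerance = 1e-12)
  eq <- pool_effects(c(0.5, 0.5, 0.5), c(0.3, 0.3, 0.3))
  expect_equal(eq$estimate, 0.5)
  expect_equal(eq$se, 0.3 / sqrt(3), tolerance = 1e-12)
  expect_equal(pool_effects(c(2, 1), c(0.2, 0.1)),
               pool_effects(c(1, 2), c(0.1, 0.2)))
  expect_error(pool_effects(c(1, 2), c(0.1, 0)), "positive")
})

test_that("Cohen's d is the pooled-sd standardised difference", {
  expect_equal(cohens_d(c(0, 1), c(0, 1)), 0)
  expect_equal(cohens_d(c(0, 1), c(1, 2)), -1 / sqrt(0.5),
               tolerance = 1e-12)
  expect_equal(cohens_d(c(1, 2), c(0, 1)), -cohens_d(c(0, 1), c(1, 2)))
  expect_error(cohens_d(c(1, 1), c(1, 1)), "zero pooled")
})

test_that("the chance-level t-test matches its closed form", {
  expect_equal(ttest_vs_chance(rep(1 / 3, 4))$t, 0)
  r <- ttest_vs_chance(c(0.5, 0.6, 0.7))
  expect_equal(r$t, (0.6 - 1 / 3) / (0.1 / sqrt(3)), tolerance = 1e-10)
  expect_equal(r$df, 2)
  # negating the deviations flips t and preserves p
  r2 <- ttest_vs_chance(1 / 3 - (c(0.5, 0.6, 0.7) - 1 / 3))
  expect_equal(r2$t, -r$t)
  expect_equal(r2$p, r$p)
})

test_that("marginal effects reduce to the main effect at zero", {
  set.seed(28)
  n <- 400
  d <- data.frame(Ct = sample(c(-1, 1), n, TRUE), P = runif(n))
  eta <- 0.4 + 0.8 * d$Ct - 0.9 * d$Ct * d$P
  d$y <- rbinom(n, 1, plogis(eta))
  fit <- glm(y ~ Ct * P, family = binomial, data = d)
  me <- marginal_effects(fit, "Ct", "Ct:P", at = c(-0.5, 0, 0.5))
  expect_equal(me$estimate[2], unname(coef(fit)["Ct"]))
  expect_equal(me$se[2], sqrt(vcov(fit)["Ct", "Ct"]), tolerance = 1e-12)
  # slopes at +/- m average to the main effect
  expect_equal(mean(me$estimate[c(1, 3)]), me$estimate[2],
               tolerance = 1e-12)
})

test_that("mixed logistic recovers a planted noise-avoidance effect", {
  gen <- function(seed, b1) {
    set.seed(seed)
    do.call(rbind, lapply(1:24, function(i) {
      X1 <- sample(c(-1, 1), 4, TRUE)
      data.frame(participant_id = i, X1 = X1,
                 Y = rbinom(4, 1, plogis(-0.1 + b1 * X1)))
    }))
  }
  fits <- vapply(1:10, function(s) {
    f <- fit_mixed_logistic(gen(s, -1), fixed = "X1")
    f$terms$estimate[f$terms$term == "X1"]
  }, numeric(1))
  expect_true(all(fits < 0))
  # permuted predictor: effect statistically indistinguishable from zero
  d0 <- gen(99, -1)
  d0$X1 <- sample(d0$X1)
  f0 <- fit_mixed_logistic(d0, fixed = "X1")
  expect_lt(abs(f0$terms$estimate[2]) / f0$terms$se[2], 3)
})

test_that("option-wise designs partition the trials", {
  sim <- cached_small_study()
  designs <- lapply(0:2, function(o) build_optionwise_design(sim$study, o))
  n_obs <- sum(sim$study$phase == "observational")
  expect_true(all(vapply(designs, nrow, integer(1)) == n_obs))
  # each trial's participant choice is counted exactly once across options
  ysum <- Reduce(`+`, lapply(designs, `[[`, "y"))
  expect_true(all(ysum == 1L))
  ct <- Reduce(`+`, lapply(designs, function(d) d$Ct == 1))
  expect_true(all(ct == 1L))
  # Rt is zero exactly on unrewarded trials, for every option
  for (d in designs) {
    expect_equal(d$Rt == 0,
                 sim$study$partner_reward[
                   sim$study$phase == "observational"] == 0)
  }
})

test_that("learning-style effects separate imitators from reward learners", {
  imitator <- learner_params(0.3, 0.5, 0.9, 8)
  rewarder <- learner_params(0.5, 0.3, 0.0, 8)
  run <- function(params, seed) {
    sim <- generate_study(small_design(10L, 2L), "full", seed = seed,
                          params_fun = function(pid) params)
    optionwise_glmm(sim$study, "P", nAGQ = 0L)
  }
  gi <- run(imitator, 61L)
  ct_i <- gi$pooled$estimate[gi$pooled$term == "Ct"]
  rt_i <- gi$pooled$estimate[gi$pooled$term == "Rt"]
  expect_gt(ct_i, rt_i)
  gr <- run(rewarder, 62L)
  ct_r <- gr$pooled$estimate[gr$pooled$term == "Ct"]
  rt_r <- gr$pooled$estimate[gr$pooled$term == "Rt"]
  expect_gt(rt_r, 0.2)
  expect_lt(abs(ct_r), rt_r)
})

test_that("the within-participant analysis keeps only dual-condition participants", {
  sim <- generate_study(small_design(12L, 4L), "full", seed = 77L)
  sel <- study_selections(sim$study)
  both <- tapply(sel$selected_partner, sel$participant_id,
                 function(x) length(unique(x)) == 2L)
  res <- optionwise_glmm(sim$study, "D", nAGQ = 0L)
  expect_equal(res$n_participants, sum(both))
  expect_true(all(c("Ct", "Rt", "D") %in% res$pooled$term))
})

test_that("bootstrap power is near the test size under a null effect", {
  set.seed(31)
  d <- data.frame(participant_id = rep(1:20, each = 4),
                  X1 = sample(c(-1, 1), 80, TRUE))
  d$Y <- rbinom(80, 1, 0.5)
  # a pure fixed-effect generator with the X1 coefficient forced to zero
  g <- glm(Y ~ X1, binomial, d)
  g$coefficients["X1"] <- 0
  set.seed(32)
  pw <- power_bootstrap(list(method = "glm_cluster", fit = g),
                        n_values = 30L, n_boot = 40L)
  expect_lt(pw$power, 0.2)
  expect_identical(nrow(pw), 1L)
})

test_that("bootstrap power grows with the sample size", {
  set.seed(33)
  d <- do.call(rbind, lapply(1:30, function(i) {
    X1 <- sample(c(-1, 1), 4, TRUE)
    data.frame(participant_id = i, X1 = X1,
               Y = rbinom(4, 1, plogis(-0.9 * X1)))
  }))
  f <- fit_mixed_logistic(d, fixed = "X1")
  set.seed(34)
  pw <- power_bootstrap(f, n_values = c(10L, 40L), n_boot = 25L)
  expect_lte(pw$power[1], pw$power[2] + 0.1)
  expect_gt(pw$power[2], 0.5)
})
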