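test_that("learner state initialises and updates per the learning rules", {
  s <- learner_state()
  expect_equal(s$V, rep(1 / 2, 3))
  expect_equal(s$A, rep(1 / 3, 3))

  s1 <- update_reward(s, 0L, 1L, 0.3)
  expect_equal(s1$V, c(0.65, 0.5, 0.5))
  expect_equal(s1$A, s$A)
  expect_equal(update_reward(s, 0L, 1L, 0)$V, s$V)

  s2 <- update_action(s, 0L, 0.3)
  expect_equal(s2$A, c(0.5333333333, 0.2333333333, 0.2333333333),
               tolerance = 1e-9)
  expect_equal(s2$V, s$V)
  expect_equal(update_action(s, 1L, 1)$A, c(0, 1, 0))
  expect_equal(update_action(s, 1L, 0)$A, s$A)
})

test_that("action tendencies stay a probability vector and values bounded", {
  set.seed(13)
  s <- learner_state()
  for (t in 1:200) {
    ch <- sample(0:2, 1)
    s <- update_reward(s, ch, sample(0:1, 1), runif(1))
    s <- update_action(s, ch, runif(1))
    expect_equal(sum(s$A), 1, tolerance = 1e-12)
    expect_true(all(s$A >= 0 & s$A <= 1))
    expect_true(all(s$V >= 0 & s$V <= 1))
  }
})

test_that("reward and action updates touch disjoint state (commute)", {
  set.seed(14)
  for (i in 1:20) {
    s <- learner_state()
    s$V <- runif(3)
    s$A <- as.vector(prop.table(runif(3)))
    ch <- sample(0:2, 1)
    r <- sample(0:1, 1)
    av <- runif(1)
    aa <- runif(1)
    ab <- update_action(update_reward(s, ch, r, av), ch, aa)
    ba <- update_reward(update_action(s, ch, aa), ch, r, av)
    expect_equal(ab, ba, tolerance = 1e-15)
  }
})

test_that("choice probabilities are uniform at initialisation and nest", {
  p <- learner_params(0.3, 0.4, 0.7, 5)
  expect_equal(choice_probs(learner_state(), p, "full"), rep(1 / 3, 3),
               tolerance = 1e-12)
  expect_equal(choice_probs(learner_state(), learner_params(1, 1, 1, 0)),
               rep(1 / 3, 3))
  set.seed(15)
  for (i in 1:20) {
    s <- learner_state()
    s$V <- runif(3)
    s$A <- as.vector(prop.table(runif(3)))
    beta <- runif(1, 0, 10)
    p1 <- learner_params(runif(1), runif(1), 1, beta)
    expect_equal(choice_probs(s, p1, "full"),
                 choice_probs(s, p1, "action_only"), tolerance = 1e-12)
    p0 <- learner_params(runif(1), runif(1), 0, beta)
    expect_equal(choice_probs(s, p0, "full"),
                 choice_probs(s, p0, "reward_only"), tolerance = 1e-12)
    expect_equal(sum(choice_probs(s, p1)), 1, tolerance = 1e-12)
  }
})

test_that("sequence log-likelihood matches a hand-stepped oracle", {
  trials <- tibble::tibble(
    block_id = 1L,
    partner_choice = c(0L, 2L, 0L),
    partner_reward = c(1L, 1L, 0L),
    participant_choice = c(0L, 2L, 1L))
  av <- 0.3; aa <- 0.2; wa <- 0.4; beta <- 2.0
  # trial 1: partner chose 0, rewarded
  V <- c(0.5, 0.5, 0.5); A <- c(1, 1, 1) / 3
  V[1] <- V[1] + av * (1 - V[1])
  A <- A + aa * (c(1, 0, 0) - A)
  Q <- (1 - wa) * V + wa * A
  p1 <- exp(beta * Q) / sum(exp(beta * Q))
  # trial 2: partner chose 2, rewarded
  V[3] <- V[3] + av * (1 - V[3])
  A <- A + aa * (c(0, 0, 1) - A)
  Q <- (1 - wa) * V + wa * A
  p2 <- exp(beta * Q) / sum(exp(beta * Q))
  # trial 3: partner chose 0, unrewarded
  V[1] <- V[1] + av * (0 - V[1])
  A <- A + aa * (c(1, 0, 0) - A)
  Q <- (1 - wa) * V + wa * A
  p3 <- exp(beta * Q) / sum(exp(beta * Q))
  oracle <- c(log(p1[1]), log(p2[3]), log(p3[2]))

  got <- sequence_loglik(learner_params(av, aa, wa, beta), trials, "full")
  expect_equal(got$pointwise, oracle, tolerance = 1e-12)
  expect_equal(got$total, sum(oracle), tolerance = 1e-12)
})

test_that("a non-learning model is uniform on its first trial", {
  trials <- tibble::tibble(block_id = 1L, partner_choice = 1L,
                           partner_reward = 1L, participant_choice = 2L)
  got <- sequence_loglik(learner_params(0, 0, 0.5, 3), trials, "full")
  expect_equal(got$total, log(1 / 3), tolerance = 1e-12)
})

test_that("full model nests the partial models at w_A boundaries", {
  set.seed(16)
  for (i in 1:100) {
    trials <- random_trials(n = 12L, n_blocks = sample(1:2, 1))
    av <- runif(1); aa <- runif(1); beta <- runif(1, 0, 10)
    l_act <- sequence_loglik(learner_params(av, aa, 1, beta), trials,
                             "full")$total
    expect_equal(l_act,
                 sequence_loglik(learner_params(av, aa, 1, beta), trials,
                                 "action_only")$total, tolerance = 1e-10)
    l_rew <- sequence_loglik(learner_params(av, aa, 0, beta), trials,
                             "full")$total
    expect_equal(l_rew,
                 sequence_loglik(learner_params(av, aa, 0, beta), trials,
                                 "reward_only")$total, tolerance = 1e-10)
  }
})

test_that("state resets at block boundaries", {
  set.seed(17)
  one <- random_trials(n = 10L)
  two <- one
  two$block_id <- 2L
  both <- dplyr::bind_rows(one, two)
  p <- random_learner_params()
  expect_equal(sequence_loglik(p, both)$total,
               2 * sequence_loglik(p, one)$total, tolerance = 1e-12)
})

test_that("simulated learners are seeded and imitate a one-sided partner", {
  partner <- tibble::tibble(block_id = 1L, partner_choice = rep(2L, 10),
                            partner_reward = rep(1L, 10))
  p <- learner_params(0.1, 0.5, 1, 400)
  set.seed(18)
  ch <- simulate_learner(p, partner)
  expect_true(all(ch[-1] == 2L))
  set.seed(19)
  a <- simulate_learner(random_learner_params(), random_trials(20))
  set.seed(19)
  b <- simulate_learner(random_learner_params(), random_trials(20))
  expect_identical(a, b)
})

test_that("the likelihood prefers the generating parameters on average", {
  set.seed(20)
  gen <- learner_params(0.4, 0.5, 0.7, 6)
  off <- learner_params(0.9, 0.1, 0.1, 1)
  diff <- replicate(60, {
    pt <- simulate_partner(partner_preset("low_noise"), n_trials = 30)
    tr <- tibble::tibble(block_id = 1L, partner_choice = pt$choice,
                         partner_reward = pt$reward)
    tr$participant_choice <- simulate_learner(gen, tr)
    sequence_loglik(gen, tr)$total - sequence_loglik(off, tr)$total
  })
  expect_gt(mean(diff), 0)
})
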