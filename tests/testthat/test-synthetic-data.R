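test_that("generative parameter draws respect their priors", {
  d <- study_design()
  set.seed(21)
  draws <- replicate(10000, unlist(draw_learner_params(d)))
  expect_true(all(draws[c("alpha_v", "alpha_a", "w_a"), ] >= 0 &
                    draws[c("alpha_v", "alpha_a", "w_a"), ] <= 1))
  expect_true(all(draws["beta", ] >= 0 & draws["beta", ] <= 30))
  # Beta(1.1, 1.1) has mean 1/2 and variance ~0.078
  se <- sqrt(0.078 / 10000)
  expect_lt(abs(mean(draws["w_a", ]) - 0.5), 3 * se)
  set.seed(22)
  a <- draw_learner_params(d)
  set.seed(22)
  expect_identical(a, draw_learner_params(d))
})

test_that("generated studies have the designed structure", {
  sim <- generate_study(small_design(4L, 2L), "full", seed = 9L)
  study <- validate_study(sim$study)
  obs <- study[study$phase == "observational", ]
  counts <- table(obs$participant_id, obs$block_id)
  expect_true(all(counts == 60L))
  expect_false(any(is.na(obs$participant_choice)))
  expect_false(any(is.na(obs$partner_choice)))
  # selection outcome consistent with the observed partner's condition
  expect_true(all(obs$selected_partner == obs$partner_noise))
  # each block shows one high- and one low-noise passive partner
  pas <- study[study$phase %in% c("passive_1", "passive_2") &
                 study$trial_index == 0, ]
  per_block <- split(pas$partner_noise,
                     interaction(pas$participant_id, pas$block_id))
  expect_true(all(vapply(per_block, function(x)
    setequal(x, c("high", "low")), logical(1))))
  # truth aligns with the dataset
  expect_equal(sort(unique(study$participant_id)),
               sim$truth$participant_id)
  sel <- study_selections(study)
  expect_equal(sel$selected_partner[sel$participant_id == 2],
               unname(unlist(sim$truth[2, c("block_1", "block_2")])))
})

test_that("generation is reproducible and participant-stable", {
  d <- small_design(3L, 2L)
  a <- generate_study(d, "full", seed = 33L)
  b <- generate_study(d, "full", seed = 33L)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_study(a$study, p1)
  write_study(b$study, p2)
  expect_identical(readLines(p1), readLines(p2))
  # adding participants never perturbs earlier participants' data
  bigger <- generate_study(small_design(5L, 2L), "full", seed = 33L)
  expect_equal(
    as.data.frame(bigger$study[bigger$study$participant_id <= 3L, ]),
    as.data.frame(a$study))
  expect_equal(as.data.frame(bigger$truth[1:3, ]),
               as.data.frame(a$truth))
})

test_that("empty designs yield empty datasets", {
  sim <- generate_study(study_design(n_participants = 0L), "full",
                        seed = 1L)
  expect_equal(nrow(sim$study), 0L)
  expect_named(sim$study, oblearn:::study_columns)
})

test_that("block-level partner assignment tracks the design probability", {
  d <- small_design(12L, 4L)
  set.seed(30)
  rates <- vapply(1:10, function(r) {
    sim <- generate_study(d, "full", seed = 1000L + r)
    sel <- study_selections(sim$study)
    mean(sel$selected_partner == "low")
  }, numeric(1))
  n_blocks <- 10 * 12 * 4
  se <- sqrt(0.7 * 0.3 / n_blocks)
  expect_lt(abs(mean(rates) - 0.7), 3 * se)
})

test_that("planted hooks override the population and selection", {
  fixed <- learner_params(0.2, 0.8, 0.9, 12)
  sim <- generate_study(small_design(3L, 2L), "full", seed = 5L,
                        params_fun = function(pid) fixed,
                        p_low_fun = function(p) 1)
  expect_true(all(sim$truth$w_a == 0.9))
  sel <- study_selections(sim$study)
  expect_true(all(sel$selected_partner == "low"))
})
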