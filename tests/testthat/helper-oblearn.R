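# Shared fixtures, built in code.  The cached objects are computed once
# per test run and reused across files.

.cache <- new.env(parent = emptyenv())

small_design <- function(n_participants = 8L, n_blocks = 2L) {
  study_design(n_participants = n_participants, n_blocks = n_blocks)
}

cached_small_study <- function() {
  if (is.null(.cache$study)) {
    .cache$study <- generate_study(small_design(), "full", seed = 42L)
  }
  .cache$study
}

cached_small_fit <- function() {
  if (is.null(.cache$fit)) {
    sim <- cached_small_study()
    .cache$fit <- fit_hierarchical(sim$study, "full", chains = 2L,
                                   warmup = 150L, iter = 150L, seed = 7L)
  }
  .cache$fit
}

# A random observational trial sequence (partner stream plus participant
# choices), for likelihood property tests.
random_trials <- function(n = 30L, n_blocks = 1L) {
  tibble::tibble(
    block_id = rep(seq_len(n_blocks), each = n),
    partner_choice = sample(0:2, n * n_blocks, replace = TRUE),
    partner_reward = sample(0:1, n * n_blocks, replace = TRUE),
    participant_choice = sample(0:2, n * n_blocks, replace = TRUE))
}

random_learner_params <- function() {
  learner_params(runif(1), runif(1), runif(1), runif(1, 0, 10))
}

# Minimal single-block study table for selection-coding tests: one
# participant-block with a chosen left/right layout and outcome.
selection_block <- function(pid, block, left_noise, left_first,
                            selected) {
  right_noise <- setdiff(c("high", "low"), left_noise)
  phase_of <- function(noise) {
    first_noise <- if (left_first) left_noise else right_noise
    if (noise == first_noise) "passive_1" else "passive_2"
  }
  side_of <- function(noise) if (noise == left_noise) "left" else "right"
  pas <- dplyr::bind_rows(lapply(c("high", "low"), function(noise) {
    tibble::tibble(participant_id = pid, block_id = block,
                   phase = phase_of(noise), trial_index = 0:1,
                   partner_noise = noise, partner_side = side_of(noise),
                   partner_choice = c(0L, 1L), partner_reward = c(1L, 0L),
                   participant_choice = NA_integer_,
                   participant_reward = NA_integer_,
                   selected_partner = NA_character_)
  }))
  obs <- tibble::tibble(participant_id = pid, block_id = block,
                        phase = "observational", trial_index = 0:1,
                        partner_noise = selected, partner_side = NA,
                        partner_choice = c(2L, 2L),
                        partner_reward = c(1L, 1L),
                        participant_choice = c(2L, 0L),
                        participant_reward = NA_integer_,
                        selected_partner = selected)
  dplyr::bind_rows(pas, obs)
}
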