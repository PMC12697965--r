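#' Study design for synthetic data generation
#'
#' Encodes the conditions of the experiment and of its recovery
#' simulations: 74 participants, 4 blocks, 30-trial passive-observation
#' sequences (two per block, one partner high-noise and one low-noise),
#' 60-trial observational-learning blocks, reward probabilities
#' 0.25/0.50/0.75, block-level probability 0.7 that the selected partner
#' is the low-noise one, and generative parameter draws
#' Beta(1.1, 1.1) for the learning rates and imitation weight and
#' Uniform(0, 30) for the inverse temperature.
#'
#' @param n_participants Number of simulated participants.
#' @param n_blocks Blocks per participant.
#' @param passive_trials Trials per passive-observation sequence.
#' @param observational_trials Trials per observational-learning block.
#' @param practice_trials Trials in each practice phase.
#' @param p_low_noise Probability that a block's selected partner is the
#'   low-noise one.
#' @param reward_probs Per-option reward probabilities.
#' @param beta_shape Shape parameters of the Beta prior on unit-interval
#'   parameters.
#' @param beta_max Upper bound of the uniform prior on the inverse
#'   temperature.
#' @return A list of class `study_design`.
#' @export
study_design <- function(n_participants = 74L, n_blocks = 4L,
                         passive_trials = 30L, observational_trials = 60L,
                         practice_trials = 60L, p_low_noise = 0.7,
                         reward_probs = c(0.25, 0.50, 0.75),
                         beta_shape = c(1.1, 1.1), beta_max = 30) {
  stopifnot(n_participants >= 0L, n_blocks >= 1L, passive_trials >= 1L,
            observational_trials >= 1L, practice_trials >= 1L,
            p_low_noise >= 0, p_low_noise <= 1)
  structure(list(n_participants = as.integer(n_participants),
                 n_blocks = as.integer(n_blocks),
                 passive_trials = as.integer(passive_trials),
                 observational_trials = as.integer(observational_trials),
                 practice_trials = as.integer(practice_trials),
                 p_low_noise = p_low_noise,
                 reward_probs = reward_probs,
                 beta_shape = beta_shape, beta_max = beta_max),
            class = "study_design")
}

#' Draw learner parameters from the generative population
#'
#' Learning rates and the imitation weight are Beta(1.1, 1.1); the inverse
#' temperature is Uniform(0, `beta_max`).
#'
#' @param design A [study_design()].
#' @return A [learner_params()].
#' @export
draw_learner_params <- function(design = study_design()) {
  b <- stats::rbeta(3, design$beta_shape[1], design$beta_shape[2])
  learner_params(alpha_v = b[1], alpha_a = b[2], w_a = b[3],
                 beta = stats::runif(1, 0, design$beta_max))
}

participant_seed <- function(seed, pid) {
  as.integer((as.numeric(seed) + 99991 * pid) %% 2147483647)
}

empty_study <- function() {
  tibble::tibble(participant_id = integer(), block_id = integer(),
                 phase = character(), trial_index = integer(),
                 partner_noise = character(), partner_side = character(),
                 partner_choice = integer(), partner_reward = integer(),
                 participant_choice = integer(),
                 participant_reward = integer(),
                 selected_partner = character())
}

trial_rows <- function(pid, block, phase, n, noise = NA_character_,
                       side = NA_character_, pc = NA_integer_,
                       pr = NA_integer_, yc = NA_integer_,
                       yr = NA_integer_, sel = NA_character_) {
  tibble::tibble(participant_id = pid, block_id = block, phase = phase,
                 trial_index = seq_len(n) - 1L, partner_noise = noise,
                 partner_side = side, partner_choice = as.integer(pc),
                 partner_reward = as.integer(pr),
                 participant_choice = as.integer(yc),
                 participant_reward = as.integer(yr),
                 selected_partner = sel)
}

#' Generate a complete synthetic study
#'
#' Per participant: learner parameters are drawn from the generative
#' population; a practice individual-learning phase is produced by a
#' Q-learning agent acting with the participant's own reward-learning rate
#' and inverse temperature; a practice observational phase pairs the
#' learner with the practice partner (inverse temperature 7.0); and each
#' main block assigns the selected partner (low-noise with probability
#' `p_low_noise`), simulates the two 30-trial passive sequences (one
#' high-noise, one low-noise partner, order and screen side randomised),
#' and simulates the 60-trial observational phase with a fresh stream from
#' the selected partner and participant choices from the learner model.
#' Each participant consumes an independent random stream derived from the
#' master seed, so adding participants never perturbs earlier ones.
#'
#' @param design A [study_design()].
#' @param kind Generating model kind (see [model_kinds()]).
#' @param seed Master seed (integer).
#' @param params_fun Optional override of the generative population: a
#'   function `(participant_id)` returning a [learner_params()] (called
#'   inside the participant's random stream).  Used to plant known
#'   parameter configurations, e.g. for identifiability studies.
#' @param p_low_fun Optional override of the selection probability: a
#'   function of the participant's [learner_params()] returning that
#'   participant's per-block probability of selecting the low-noise
#'   partner.  Used to plant associations between learning style and
#'   partner preference; the default is the exogenous
#'   `design$p_low_noise` coin flip.
#' @return A list with `study` (tidy trial table) and `truth` (one row per
#'   participant: generating parameters, model kind, and per-block
#'   selected-partner conditions).
#' @export
generate_study <- function(design = study_design(), kind = "full",
                           seed = 1L, params_fun = NULL,
                           p_low_fun = NULL) {
  kind <- match.arg(kind, model_kinds())
  rows <- vector("list", design$n_participants)
  truths <- vector("list", design$n_participants)
  rs <- reward_structure(design$reward_probs)

  for (pid in seq_len(design$n_participants)) {
    set.seed(participant_seed(seed, pid))
    params <- if (is.null(params_fun)) draw_learner_params(design) else
      params_fun(pid)
    p_low <- if (is.null(p_low_fun)) design$p_low_noise else
      p_low_fun(params)
    prows <- list()

    # practice individual learning: own choices, own visible outcomes
    own <- simulate_partner(q_agent_params(params$alpha_v, params$beta), rs,
                            design$practice_trials)
    prows$pi <- trial_rows(pid, 0L, "practice_individual",
                           design$practice_trials,
                           yc = own$choice, yr = own$reward)

    # practice observational learning with the practice partner
    pp <- simulate_partner(partner_preset("practice"), rs,
                           design$practice_trials)
    po <- data.frame(partner_choice = pp$choice, partner_reward = pp$reward,
                     block_id = 0L)
    prows$po <- trial_rows(pid, 0L, "practice_observational",
                           design$practice_trials, pc = pp$choice,
                           pr = pp$reward,
                           yc = simulate_learner(params, po, kind))

    sel_cond <- character(design$n_blocks)
    for (b in seq_len(design$n_blocks)) {
      sel_cond[b] <- if (stats::runif(1) < p_low) "low" else "high"
      first_high <- stats::runif(1) < 0.5
      order_noise <- if (first_high) c("high", "low") else c("low", "high")
      left_high <- stats::runif(1) < 0.5
      side_of <- c(high = if (left_high) "left" else "right",
                   low = if (left_high) "right" else "left")
      for (k in 1:2) {
        noise <- order_noise[k]
        pt <- simulate_partner(partner_preset(paste0(noise, "_noise")), rs,
                               design$passive_trials)
        prows[[paste0("pa", b, k)]] <- trial_rows(
          pid, b, paste0("passive_", k), design$passive_trials,
          noise = noise, side = side_of[[noise]],
          pc = pt$choice, pr = pt$reward)
      }
      ot <- simulate_partner(partner_preset(paste0(sel_cond[b], "_noise")),
                             rs, design$observational_trials)
      od <- data.frame(partner_choice = ot$choice,
                       partner_reward = ot$reward, block_id = b)
      prows[[paste0("ob", b)]] <- trial_rows(
        pid, b, "observational", design$observational_trials,
        noise = sel_cond[b], pc = ot$choice, pr = ot$reward,
        yc = simulate_learner(params, od, kind), sel = sel_cond[b])
    }

    rows[[pid]] <- dplyr::bind_rows(prows)
    tr <- tibble::tibble(participant_id = pid, model_kind = kind,
                         alpha_v = params$alpha_v, alpha_a = params$alpha_a,
                         w_a = params$w_a, beta = params$beta)
    for (b in seq_len(design$n_blocks)) {
      tr[[paste0("block_", b)]] <- sel_cond[b]
    }
    truths[[pid]] <- tr
  }

  study <- if (design$n_participants == 0L) empty_study() else
    dplyr::bind_rows(rows)
  truth <- if (design$n_participants == 0L) tibble::tibble() else
    dplyr::bind_rows(truths)
  list(study = study, truth = truth)
}

#' Write the ground-truth table of a synthetic study
#'
#' @param truth The `truth` component of [generate_study()].
#' @param path Output CSV path.
#' @export
write_truth <- function(truth, path) {
  utils::write.csv(as.data.frame(truth), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
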