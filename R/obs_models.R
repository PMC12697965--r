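#' Observational-learning model parameters
#'
#' The Full model carries two learning systems.  A Reward Learning
#' component updates per-option action values `V` from the partner's
#' observed outcomes via a delta rule with rate `alpha_v`; an Action
#' Learning component updates action tendencies `A` toward the partner's
#' choices with rate `alpha_a`.  At decision time the two are mixed,
#' `Q = (1 - w_a) V + w_a A`, and a softmax with inverse temperature
#' `beta` maps `Q` to choice probabilities.  The partial models drop one
#' component: the Action Learning model chooses by softmax over `A` alone
#' (ignoring `alpha_v`, `w_a`), the Reward Learning model over `V` alone.
#'
#' @param alpha_v Reward-learning rate in `[0, 1]`.
#' @param alpha_a Action-learning rate in `[0, 1]`.
#' @param w_a Imitation weight in `[0, 1]`.
#' @param beta Inverse temperature, `>= 0`.
#' @return A list of class `learner_params`.
#' @export
learner_params <- function(alpha_v, alpha_a, w_a, beta) {
  vals <- c(alpha_v = alpha_v, alpha_a = alpha_a, w_a = w_a)
  if (any(vals < 0 | vals > 1)) {
    stop("alpha_v, alpha_a and w_a must lie in [0, 1]")
  }
  stopifnot(beta >= 0)
  structure(list(alpha_v = alpha_v, alpha_a = alpha_a, w_a = w_a,
                 beta = beta), class = "learner_params")
}

#' Model kinds
#'
#' @return Character vector of the three model names.
#' @export
model_kinds <- function() c("full", "action_only", "reward_only")

kind_code <- function(kind) {
  kind <- match.arg(kind, model_kinds())
  c(full = 0L, action_only = 1L, reward_only = 2L)[[kind]]
}

#' Initial learner state
#'
#' Action values start at 1/2 (the midpoint of the unit reward scale) and
#' action tendencies at 1/3 (uniform over the three options); the state is
#' re-initialised at every block boundary because stimuli and reward
#' assignments are re-randomised across blocks.
#'
#' @return A list with numeric vectors `V` and `A`.
#' @export
learner_state <- function() {
  list(V = rep(1 / 2, 3), A = rep(1 / 3, 3))
}

#' Reward-learning update (vicarious delta rule)
#'
#' @param state A learner state (see [learner_state()]).
#' @param partner_choice 0-based option the partner chose.
#' @param reward The partner's reward in \{0, 1\}.
#' @param alpha_v Reward-learning rate.
#' @return The updated state; `A` is untouched.
#' @export
update_reward <- function(state, partner_choice, reward, alpha_v) {
  i <- check_option(partner_choice) + 1L
  stopifnot(reward %in% c(0, 1))
  state$V[i] <- state$V[i] + alpha_v * (reward - state$V[i])
  state
}

#' Action-learning update (imitation tendencies)
#'
#' The chosen option's tendency moves toward 1 and every unchosen option's
#' toward 0, all by fraction `alpha_a`.  The update is an affine
#' contraction toward a probability vector, so `sum(A) == 1` is preserved
#' exactly.
#'
#' @param state A learner state.
#' @param partner_choice 0-based option the partner chose.
#' @param alpha_a Action-learning rate.
#' @return The updated state; `V` is untouched.
#' @export
update_action <- function(state, partner_choice, alpha_a) {
  i <- check_option(partner_choice) + 1L
  target <- c(0, 0, 0)
  target[i] <- 1
  state$A <- state$A + alpha_a * (target - state$A)
  state
}

#' Choice probabilities of an observational-learning model
#'
#' @param state A learner state.
#' @param params A [learner_params()].
#' @param kind One of `"full"`, `"action_only"`, `"reward_only"`.
#' @return Probability vector over the three options, summing to 1.
#' @export
choice_probs <- function(state, params, kind = "full") {
  kind <- match.arg(kind, model_kinds())
  q <- switch(kind,
    full = (1 - params$w_a) * state$V + params$w_a * state$A,
    action_only = state$A,
    reward_only = state$V
  )
  softmax_choice(q, params$beta)
}

prep_obs_trials <- function(trials) {
  need <- c("partner_choice", "partner_reward", "participant_choice")
  missing <- setdiff(need, names(trials))
  if (length(missing) > 0L) {
    stop("trials lack column(s): ", paste(missing, collapse = ", "))
  }
  bad <- which(is.na(trials$partner_choice) | is.na(trials$partner_reward) |
                 is.na(trials$participant_choice))
  if (length(bad) > 0L) {
    stop("trial ", bad[1L], " has missing partner or participant fields")
  }
  if (is.null(trials$block_id)) trials$block_id <- 0L
  # reset indices: first trial of each block (0-based for C++)
  starts <- which(c(TRUE, trials$block_id[-1L] !=
                      trials$block_id[-nrow(trials)])) - 1L
  list(pc = as.integer(trials$partner_choice),
       pr = as.integer(trials$partner_reward),
       yc = as.integer(trials$participant_choice),
       starts = as.integer(starts))
}

#' Log-likelihood of a participant's observational choices
#'
#' Each trial the partner acts first: the partner's choice and reward are
#' incorporated into the learner state, and the participant's choice is
#' then evaluated under the updated state.  The state resets to its
#' initial values at every block boundary (a change in `block_id`).
#'
#' @param params A [learner_params()].
#' @param trials A data frame with `partner_choice`, `partner_reward`,
#'   `participant_choice` and (optionally) `block_id`, in trial order.
#' @param kind Model kind.
#' @return A list with `total` (the summed log-likelihood) and `pointwise`
#'   (the per-trial vector).
#' @export
sequence_loglik <- function(params, trials, kind = "full") {
  kind <- match.arg(kind, model_kinds())
  d <- prep_obs_trials(trials)
  ll <- obs_loglik_cpp(d$pc, d$pr, d$yc, d$starts,
                       params$alpha_v, params$alpha_a, params$w_a,
                       params$beta, kind_code(kind))
  list(total = sum(ll), pointwise = ll)
}

#' Simulate a learner observing a partner stream
#'
#' Generates participant choices trial by trial: the partner's choice and
#' reward update the state, then a choice is sampled from the model's
#' choice probabilities.  The participant's own (hidden) outcome never
#' feeds back into the state.
#'
#' @param params A [learner_params()].
#' @param partner_trials Data frame with `partner_choice`,
#'   `partner_reward` and optionally `block_id` (state resets per block).
#' @param kind Model kind.
#' @return Integer vector of simulated 0-based participant choices.
#' @export
simulate_learner <- function(params, partner_trials, kind = "full") {
  kind <- match.arg(kind, model_kinds())
  n <- nrow(partner_trials)
  block <- if (is.null(partner_trials$block_id)) rep(0L, n) else
    partner_trials$block_id
  out <- integer(n)
  state <- learner_state()
  for (t in seq_len(n)) {
    if (t == 1L || block[t] != block[t - 1L]) state <- learner_state()
    state <- update_reward(state, partner_trials$partner_choice[t],
                           partner_trials$partner_reward[t], params$alpha_v)
    state <- update_action(state, partner_trials$partner_choice[t],
                           params$alpha_a)
    p <- choice_probs(state, params, kind)
    out[t] <- sample.int(3L, 1L, prob = p) - 1L
  }
  out
}
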