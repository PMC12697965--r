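#' Softmax choice probabilities
#'
#' Numerically stable softmax over `beta * values`; `beta = 0` gives the
#' uniform distribution, large `beta` approaches the argmax.
#'
#' @param values Numeric vector of option values.
#' @param beta Inverse temperature, `>= 0`.
#' @return Probability vector summing to 1.
#' @export
softmax_choice <- function(values, beta) {
  z <- beta * values
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Simulated partner presets
#'
#' The partners observed in the task are standard Q-learning agents that
#' differ only in decision noise: the high-noise partner uses inverse
#' temperature 1.5, the low-noise partner 20.0, and the practice-block
#' partner 7.0; all share learning rate 0.3.
#'
#' @param condition One of `"high_noise"`, `"low_noise"`, `"practice"`.
#' @return A list with elements `alpha` and `beta`.
#' @export
partner_preset <- function(condition = c("high_noise", "low_noise",
                                         "practice")) {
  condition <- match.arg(condition)
  beta <- switch(condition, high_noise = 1.5, low_noise = 20.0,
                 practice = 7.0)
  q_agent_params(alpha = 0.3, beta = beta)
}

#' Q-learning agent parameters
#'
#' @param alpha Learning rate in `[0, 1]`.
#' @param beta Inverse temperature, `>= 0`.
#' @return A list of class `q_agent_params`.
#' @export
q_agent_params <- function(alpha, beta) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha >= 0, alpha <= 1,
            is.numeric(beta), length(beta) == 1L, beta >= 0)
  structure(list(alpha = alpha, beta = beta), class = "q_agent_params")
}

#' Delta-rule value update
#'
#' The chosen option's value moves toward the obtained reward by a fraction
#' `alpha`; all other values are untouched.
#'
#' @param q Numeric vector of per-option values.
#' @param choice 0-based chosen option.
#' @param reward Reward in \{0, 1\}.
#' @param alpha Learning rate.
#' @return The updated value vector.
#' @export
q_update <- function(q, choice, reward, alpha) {
  choice <- check_option(choice)
  stopifnot(reward %in% c(0, 1))
  q[choice + 1L] <- q[choice + 1L] + alpha * (reward - q[choice + 1L])
  q
}

#' Simulate a Q-learning partner on the bandit
#'
#' Generates the choice/reward stream of a simulated partner: on every
#' trial the agent picks an option by softmax over its Q values, draws a
#' Bernoulli reward from the bandit, and applies the delta rule.  Q values
#' start at 0.5, the midpoint of the unit reward scale.
#'
#' @param params A [q_agent_params()] (or [partner_preset()]).
#' @param structure A [reward_structure()].
#' @param n_trials Number of trials (`>= 1`).
#' @return A tibble with `trial_index` (0-based), `choice`, `reward`.
#' @export
simulate_partner <- function(params, structure = reward_structure(),
                             n_trials = 30L) {
  stopifnot(n_trials >= 1L)
  q <- rep(0.5, 3)
  choice <- integer(n_trials)
  reward <- integer(n_trials)
  for (t in seq_len(n_trials)) {
    p <- softmax_choice(q, params$beta)
    choice[t] <- sample.int(3L, 1L, prob = p) - 1L
    reward[t] <- sample_reward(choice[t], structure)
    q <- q_update(q, choice[t], reward[t], params$alpha)
  }
  tibble::tibble(trial_index = seq_len(n_trials) - 1L,
                 choice = choice, reward = reward)
}

#' Information-bonus RL model parameters
#'
#' A Q-learning model with a count-based exploration incentive: the value
#' used for choice is `q_X + kappa / N_X`, where `N_X` counts how often
#' option X has been chosen (pseudo-count starting at 1).  This model plays
#' two roles: fitted to a participant's own individual-learning choices it
#' defines that participant's decision process, and applied to a partner's
#' observed sequence it yields the predictability and information-gain
#' partner metrics.
#'
#' @param alpha Learning rate in `[0, 1]`.
#' @param beta Inverse temperature, `>= 0`.
#' @param kappa Information-bonus weight in `[0, 1]`.
#' @return A list of class `info_bonus_params`.
#' @export
info_bonus_params <- function(alpha, beta, kappa) {
  stopifnot(alpha >= 0, alpha <= 1, beta >= 0, kappa >= 0, kappa <= 1)
  structure(list(alpha = alpha, beta = beta, kappa = kappa),
            class = "info_bonus_params")
}

#' Bonus-augmented option values
#'
#' @param q Per-option value vector.
#' @param n Per-option choice counts (pseudo-counts, `>= 1`).
#' @param kappa Information-bonus weight.
#' @return `q + kappa / n`.
#' @export
info_bonus_values <- function(q, n, kappa) {
  stopifnot(all(n >= 1))
  q + kappa / n
}

#' Total information gain of an observed choice sequence
#'
#' Every choice of option X shrinks its information bonus from
#' `kappa / N_X` to `kappa / (N_X + 1)`; the information gain of a sequence
#' is the summed reduction.  Because the per-trial decrements telescope,
#' the total depends only on the per-option choice counts `c_X`:
#' `kappa * sum_X (1 - 1 / (c_X + 1))`.
#'
#' @param choices Integer vector of 0-based partner choices.
#' @param kappa Information-bonus weight in `[0, 1]`.
#' @return Total gain, `>= 0`.
#' @export
information_gain <- function(choices, kappa) {
  stopifnot(kappa >= 0, kappa <= 1)
  choices <- check_option(choices)
  n <- rep(1, 3)
  gain <- 0
  for (ch in choices) {
    i <- ch + 1L
    gain <- gain + kappa * (1 / n[i] - 1 / (n[i] + 1))
    n[i] <- n[i] + 1
  }
  gain
}
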