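practice_data_by_participant <- function(study) {
  trials <- study[study$phase == "practice_individual", ]
  if (nrow(trials) == 0L) stop("no practice individual-learning trials")
  bad <- is.na(trials$participant_choice) | is.na(trials$participant_reward)
  if (any(bad)) stop("practice trial ", which(bad)[1L],
                     " lacks a choice or reward")
  trials <- trials[order(trials$participant_id, trials$trial_index), ]
  ids <- unique(trials$participant_id)
  dat <- lapply(ids, function(id) {
    tr <- trials[trials$participant_id == id, ]
    list(ch = as.integer(tr$participant_choice),
         rw = as.integer(tr$participant_reward), starts = 0L)
  })
  names(dat) <- ids
  list(ids = ids, data = dat)
}

#' Fit the information-bonus RL model to practice data
#'
#' Hierarchically fits each participant's own individual-learning choices
#' with a Q-learning model carrying a count-based information bonus
#' (`kappa / N_X` added to the chosen value at decision time).  The same
#' raw-scale population model, hyperpriors and sampler as
#' [fit_hierarchical()] are used; `alpha` and `kappa` get the logistic
#' transform, `beta` the exponential.  The per-participant posterior-mean
#' parameters define the participant-specific decision process used by
#' [predictability()].
#'
#' @inheritParams fit_hierarchical
#' @return An `oblearn_fit` whose `posterior_means` has columns `alpha`,
#'   `beta`, `kappa`.
#' @export
fit_practice_model <- function(study, chains = 4L, warmup = 1000L,
                               iter = 1000L, seed = 1L) {
  roles <- model_roles("info_bonus")
  dat <- practice_data_by_participant(study)
  n_subj <- length(dat$ids)
  lens <- vapply(dat$data, function(d) length(d$ch), integer(1))
  subj_start <- c(0L, cumsum(lens))
  cat_ch <- unlist(lapply(dat$data, `[[`, "ch"), use.names = FALSE)
  cat_rw <- unlist(lapply(dat$data, `[[`, "rw"), use.names = FALSE)
  cat_starts <- subj_start[-length(subj_start)]
  loglik_batch <- function(nat) {
    info_loglik_batch_cpp(cat_ch, cat_rw, cat_starts, subj_start, nat)
  }
  draws <- hier_mcmc(loglik_batch, n_subj, roles, chains, warmup, iter,
                     seed)
  fit <- finalize_fit(draws, dat, "info_bonus", roles, chains, iter,
                      pointwise_fun = function(d, nat_mat) {
                        info_loglik_draws_cpp(d$ch, d$rw, d$starts, nat_mat)
                      })
  fit
}

#' Partner performance in a passive-observation sequence
#'
#' @param rewards Integer 0/1 rewards of the partner's trials.
#' @return Total obtained reward (an integer count).
#' @export
performance <- function(rewards) {
  stopifnot(all(rewards %in% c(0, 1)))
  sum(as.integer(rewards))
}

#' Predictability of a partner under a participant's decision model
#'
#' The log-likelihood (natural log, always `<= 0`) that the
#' participant-specific information-bonus RL model generates the partner's
#' observed choice sequence; the model's state is updated along the
#' sequence by the partner's own choices and rewards (the observer sees
#' both).  Higher values mean the partner behaves more like the
#' participant's own decision process.
#'
#' @param params An [info_bonus_params()] (e.g. a participant's
#'   posterior-mean practice-fit parameters).
#' @param choices Partner's 0-based choices in trial order.
#' @param rewards Partner's 0/1 rewards.
#' @return Summed log-likelihood.
#' @export
predictability <- function(params, choices, rewards) {
  stopifnot(length(choices) == length(rewards))
  sum(info_loglik_cpp(as.integer(choices), as.integer(rewards), 0L,
                      params$alpha, params$beta, params$kappa))
}

#' Block-level partner metrics
#'
#' One row per participant, block and screen side with the three indices
#' the selection analysis uses: performance (total passive-phase reward),
#' predictability (log-likelihood of the partner's choices under the
#' participant's practice-fitted information-bonus model), and information
#' gain (total bonus reduction induced by the partner's choices at the
#' participant's fitted `kappa`).
#'
#' @param study A validated study table.
#' @param practice_fit The [fit_practice_model()] result for the same
#'   study.
#' @return A tibble with columns `participant_id`, `block_id`, `side`,
#'   `noise`, `performance`, `predictability`, `information_gain`.
#' @export
partner_metrics <- function(study, practice_fit) {
  pm <- practice_fit$posterior_means
  passive <- study[study$phase %in% c("passive_1", "passive_2"), ]
  if (nrow(passive) == 0L) stop("no passive-observation trials")
  key <- unique(passive[, c("participant_id", "block_id", "phase",
                            "partner_noise", "partner_side")])
  rows <- lapply(seq_len(nrow(key)), function(r) {
    tr <- passive[passive$participant_id == key$participant_id[r] &
                    passive$block_id == key$block_id[r] &
                    passive$phase == key$phase[r], ]
    tr <- tr[order(tr$trial_index), ]
    p <- pm[pm$participant_id == key$participant_id[r], ]
    if (nrow(p) != 1L) stop("no practice fit for participant ",
                            key$participant_id[r])
    ib <- info_bonus_params(p$alpha, p$beta, p$kappa)
    tibble::tibble(
      participant_id = key$participant_id[r], block_id = key$block_id[r],
      side = key$partner_side[r], noise = key$partner_noise[r],
      performance = performance(tr$partner_reward),
      predictability = predictability(ib, tr$partner_choice,
                                      tr$partner_reward),
      information_gain = information_gain(tr$partner_choice, p$kappa))
  })
  dplyr::bind_rows(rows)
}

#' Right-minus-left difference regressors for partner selection
#'
#' For every block, subtracts the left-hand partner's score from the
#' right-hand partner's for each of the three indices, then z-standardises
#' each difference across all participant-blocks pooled.
#'
#' @param metrics Output of [partner_metrics()].
#' @return A tibble with one row per participant-block: raw differences
#'   (`d_performance`, `d_predictability`, `d_information_gain`) and their
#'   z-scored versions (`z_*`).
#' @export
selection_regressors <- function(metrics) {
  left <- metrics[metrics$side == "left", ]
  right <- metrics[metrics$side == "right", ]
  key <- c("participant_id", "block_id")
  m <- merge(as.data.frame(left), as.data.frame(right), by = key,
             suffixes = c("_left", "_right"))
  out <- tibble::tibble(
    participant_id = m$participant_id, block_id = m$block_id,
    d_performance = m$performance_right - m$performance_left,
    d_predictability = m$predictability_right - m$predictability_left,
    d_information_gain = m$information_gain_right -
      m$information_gain_left)
  for (v in c("d_performance", "d_predictability", "d_information_gain")) {
    s <- stats::sd(out[[v]])
    if (!is.finite(s) || s == 0) {
      stop("zero variance in index ", sub("^d_", "", v),
           "; cannot z-standardise")
    }
    out[[sub("^d_", "z_", v)]] <- (out[[v]] - mean(out[[v]])) / s
  }
  out[order(out$participant_id, out$block_id), ]
}
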