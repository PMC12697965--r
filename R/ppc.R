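#' Observational-phase learning curve
#'
#' The per-trial proportion of correct choices (the option with the
#' highest reward probability) averaged over participants and blocks.
#'
#' @param study A study table with observational trials.
#' @param structure The bandit's [reward_structure()].
#' @return A tibble with `trial_index` and `prop_correct`.
#' @export
learning_curve <- function(study, structure = reward_structure()) {
  obs <- study[study$phase == "observational", ]
  if (nrow(obs) == 0L) stop("no observational trials")
  best <- best_option(structure)
  agg <- stats::aggregate(
    list(prop_correct = obs$participant_choice == best),
    by = list(trial_index = obs$trial_index), FUN = mean)
  tibble::as_tibble(agg[order(agg$trial_index), ])
}

ppc_glmm <- function(rep_obs, pref, nAGQ = 1L) {
  fits <- lapply(0:2, function(opt) {
    d <- build_optionwise_design(rep_obs, opt)
    d <- tibble::as_tibble(merge(as.data.frame(d), as.data.frame(pref),
                                 by = "participant_id"))
    names(d)[names(d) == "pref_high"] <- "P"
    fit_mixed_logistic(d, outcome = "y",
                       fixed = c("Ct", "Rt", "P", "Ct:P", "Rt:P"),
                       random = c("Ct", "Rt"), nAGQ = nAGQ)
  })
  terms <- fits[[1]]$terms$term
  dplyr::bind_rows(lapply(terms, function(tm) {
    est <- vapply(fits, function(f)
      f$terms$estimate[f$terms$term == tm], numeric(1))
    se <- vapply(fits, function(f) f$terms$se[f$terms$term == tm],
                 numeric(1))
    p <- pool_effects(est, se)
    tibble::tibble(term = tm, estimate = p$estimate, se = p$se)
  }))
}

#' Posterior predictive checks for the Full model
#'
#' Regenerates the study from the fitted individual parameters and
#' recomputes the behavioural summaries.  Per replicate, every
#' participant's choices are re-simulated for all their blocks under the
#' same conditions as the original data (same selected-partner noise
#' level, trial counts and reward contingencies; partner streams are
#' regenerated from the partner parameters, not replayed), using the
#' participant's posterior-mean parameters (or one posterior draw per
#' replicate with `use = "draw"`).  Each replicate yields a learning
#' curve and, optionally, the pooled learning-style GLMM effects refitted
#' on the simulated choices.
#'
#' @param fit A full-model [fit_hierarchical()] result.
#' @param study The originating study table.
#' @param n_reps Number of posterior predictive replicates.
#' @param seed Integer seed.
#' @param refit_glmm Refit the option-wise GLMM per replicate (slower).
#' @param use `"mean"` (posterior means, deterministic across replicates)
#'   or `"draw"` (one joint posterior draw per replicate).
#' @param nAGQ Passed to the GLMM refits.
#' @return A list of class `ppc_result`: `curves` (replicates x trials
#'   matrix), `curve_mean`, `curve_sd` (NA with a flag when
#'   `n_reps == 1`), and if requested `effects` (per-replicate pooled
#'   GLMM estimates) with across-replicate `effect_summary`.
#' @export
run_ppc <- function(fit, study, n_reps = 500L, seed = 1L,
                    refit_glmm = TRUE, use = c("mean", "draw"),
                    nAGQ = 1L) {
  use <- match.arg(use)
  if (fit$kind != "full") stop("posterior predictive checks use the ",
                               "full-model fit")
  set.seed(as.integer(seed))
  obs <- study[study$phase == "observational", ]
  obs <- obs[order(obs$participant_id, obs$block_id, obs$trial_index), ]
  conds <- unique(obs[, c("participant_id", "block_id", "partner_noise")])
  n_trials <- max(obs$trial_index) + 1L
  pref <- high_noise_preference(study)
  pm <- fit$posterior_means
  rs <- reward_structure()

  flat <- matrix(fit$draws, nrow = dim(fit$draws)[1] * dim(fit$draws)[2],
                 dimnames = list(NULL, dimnames(fit$draws)[[3]]))
  draw_params <- function(pid) {
    i <- match(pid, fit$participants)
    if (use == "mean") {
      r <- pm[pm$participant_id == pid, ]
      learner_params(r$alpha_v, r$alpha_a, r$w_a, r$beta)
    } else {
      d <- sample.int(nrow(flat), 1L)
      learner_params(to_natural(flat[d, paste0("alpha_v[", i, "]")], "unit"),
                     to_natural(flat[d, paste0("alpha_a[", i, "]")], "unit"),
                     to_natural(flat[d, paste0("w_a[", i, "]")], "unit"),
                     to_natural(flat[d, paste0("beta[", i, "]")],
                                "positive"))
    }
  }

  curves <- matrix(NA_real_, n_reps, n_trials)
  effects <- list()
  for (rep in seq_len(n_reps)) {
    sim_rows <- lapply(seq_len(nrow(conds)), function(r) {
      pid <- conds$participant_id[r]
      noise <- conds$partner_noise[r]
      pt <- simulate_partner(partner_preset(paste0(noise, "_noise")), rs,
                             n_trials)
      od <- data.frame(partner_choice = pt$choice,
                       partner_reward = pt$reward,
                       block_id = conds$block_id[r])
      params <- draw_params(pid)
      tibble::tibble(participant_id = pid, block_id = conds$block_id[r],
                     phase = "observational",
                     trial_index = pt$trial_index, partner_noise = noise,
                     partner_choice = pt$choice, partner_reward = pt$reward,
                     participant_choice = simulate_learner(params, od,
                                                           "full"))
    })
    rep_obs <- dplyr::bind_rows(sim_rows)
    curves[rep, ] <- learning_curve(rep_obs, rs)$prop_correct
    if (refit_glmm) {
      effects[[rep]] <- cbind(rep = rep, ppc_glmm(rep_obs, pref, nAGQ))
    }
  }

  out <- list(curves = curves, curve_mean = colMeans(curves),
              curve_sd = if (n_reps > 1L) apply(curves, 2, stats::sd) else
                rep(NA_real_, n_trials),
              sd_defined = n_reps > 1L, n_reps = n_reps)
  if (refit_glmm) {
    eff <- dplyr::bind_rows(effects)
    out$effects <- eff
    agg_m <- stats::aggregate(list(mean = eff$estimate),
                              by = list(term = eff$term), FUN = mean)
    agg_s <- stats::aggregate(list(sd = eff$estimate),
                              by = list(term = eff$term), FUN = stats::sd)
    out$effect_summary <- tibble::as_tibble(merge(agg_m, agg_s,
                                                  by = "term"))
  }
  structure(out, class = "ppc_result")
}

#' @export
print.ppc_result <- function(x, ...) {
  cat("<ppc_result>", x$n_reps, "replicates,", length(x$curve_mean),
      "trials\n")
  cat(sprintf("  final-trial accuracy %.3f (sd %.3f)\n",
              x$curve_mean[length(x$curve_mean)],
              x$curve_sd[length(x$curve_sd)]))
  if (!x$sd_defined) cat("  note: SDs undefined with a single replicate\n")
  invisible(x)
}
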