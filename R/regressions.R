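#' Design matrix for the partner-selection regressions
#'
#' One row per participant-block.  The outcome `Y` is 1 when the left-hand
#' partner was chosen.  `X1` is +1 when the high-noise partner appeared on
#' the left and -1 when on the right, so a negative `X1` coefficient means
#' the high-noise partner was avoided.  `X2` is +1 when the left-hand
#' partner was presented first in the passive-observation phase,
#' controlling for order bias; the intercept captures spatial bias.  The
#' `"factors"` variant replaces `X1` with three z-scored right-minus-left
#' difference regressors (performance, predictability, information gain)
#' from [selection_regressors()].
#'
#' @param study A validated study table.
#' @param which `"model1"` (X1 only), `"model2"` (X1 + X2) or `"factors"`.
#' @param regressors For `"factors"`: the output of
#'   [selection_regressors()].
#' @return A tibble with the outcome, coded predictors and participant id.
#' @export
build_selection_design <- function(study,
                                   which = c("model1", "model2", "factors"),
                                   regressors = NULL) {
  which <- match.arg(which)
  sel <- study_selections(study)
  if (any(is.na(sel$selected_partner))) {
    stop("missing selection outcome in block ",
         sel$block_id[which(is.na(sel$selected_partner))[1L]])
  }
  out <- tibble::tibble(
    participant_id = sel$participant_id, block_id = sel$block_id,
    Y = as.integer(sel$chose_left),
    X1 = ifelse(sel$left_noise == "high", 1, -1),
    X2 = ifelse(sel$left_first, 1, -1))
  if (which == "model1") return(out[, c("participant_id", "block_id",
                                        "Y", "X1")])
  if (which == "model2") return(out)
  if (is.null(regressors)) {
    stop("the factors design needs the selection_regressors() table")
  }
  out$X1 <- NULL
  merge_cols <- c("participant_id", "block_id")
  z <- regressors[, c(merge_cols, "z_performance", "z_predictability",
                      "z_information_gain")]
  tibble::as_tibble(merge(as.data.frame(out), as.data.frame(z),
                          by = merge_cols))
}

# Cluster-robust (CR0) covariance of a glm by participant.
cluster_vcov <- function(fit, cluster) {
  X <- stats::model.matrix(fit)
  u <- stats::residuals(fit, type = "response")
  scores <- X * u
  meat <- Reduce(`+`, lapply(split.data.frame(scores, cluster), function(s) {
    cs <- colSums(s)
    tcrossprod(cs)
  }))
  bread <- stats::vcov(fit) / summary(fit)$dispersion
  bread %*% meat %*% bread
}

glmer_converged <- function(fit) {
  msgs <- unlist(fit@optinfo$conv$lme4$messages)
  length(msgs) == 0L || !any(grepl("failed to converge", msgs))
}

term_table <- function(est, se, n_subj, method) {
  t <- est / se
  tibble::tibble(term = names(est), estimate = unname(est),
                 se = unname(se), stat = unname(t), df = n_subj,
                 p = 2 * stats::pt(-abs(t), df = n_subj), method = method)
}

#' Fit a mixed-effects logistic regression
#'
#' Fits `outcome ~ fixed terms` with by-participant random intercepts and
#' random slopes, via `lme4::glmer`.  Coefficient significance is
#' assessed with two-tailed t-tests against zero using the number of
#' participants as degrees of freedom (a reporting convention, not a
#' derived quantity).  If the random-effects fit fails or does not
#' converge, the function falls back to a fixed-effects logistic
#' regression with cluster-robust standard errors by participant; the
#' `method` column flags which route produced each estimate.
#'
#' @param design A data frame with the outcome, predictors and
#'   `participant_id`.
#' @param outcome Name of the 0/1 outcome column.
#' @param fixed Character vector of fixed-effect term labels (may include
#'   interactions like `"Ct:P"`).
#' @param random Character vector of random-slope terms (random intercept
#'   always included).
#' @param nAGQ Integer passed to `glmer` (0 = faster penalised
#'   quasi-likelihood-style fit, 1 = Laplace).
#' @return A list with `terms` (tibble: term, estimate, se, stat, df, p,
#'   method), `fit` (the underlying model object) and `method`.
#' @export
fit_mixed_logistic <- function(design, outcome = "Y", fixed = "X1",
                               random = fixed, nAGQ = 1L) {
  n_subj <- length(unique(design$participant_id))
  if (n_subj < 2L) stop("need at least 2 participants")
  fix_part <- if (length(fixed) == 0L) "1" else
    paste(c("1", fixed), collapse = " + ")
  re_part <- paste(c("1", random), collapse = " + ")
  form <- stats::as.formula(sprintf("%s ~ %s + (%s | participant_id)",
                                    outcome, fix_part, re_part))
  fit <- tryCatch(
    lme4::glmer(form, data = design, family = stats::binomial,
                nAGQ = nAGQ,
                control = lme4::glmerControl(optimizer = "bobyqa",
                                             calc.derivs = FALSE)),
    error = function(e) NULL, warning = function(w) NULL)
  if (!is.null(fit) && glmer_converged(fit)) {
    est <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    return(list(terms = term_table(est, se, n_subj, "glmer"),
                fit = fit, method = "glmer"))
  }
  gform <- stats::as.formula(sprintf("%s ~ %s", outcome, fix_part))
  gfit <- stats::glm(gform, data = design, family = stats::binomial)
  vc <- cluster_vcov(gfit, design$participant_id)
  est <- stats::coef(gfit)
  se <- sqrt(diag(vc))
  list(terms = term_table(est, se, n_subj, "glm_cluster"), fit = gfit,
       method = "glm_cluster")
}

#' Option-wise learning-style design
#'
#' Builds, for one option X, the trial-level design of the learning-style
#' regression: the outcome is 1 when the participant chose X; `Ct` codes
#' the partner's choice on the trial (+1 chose X, -1 otherwise); `Rt`
#' codes the partner's outcome relative to X (+1 rewarded for X, -1
#' rewarded for another option, 0 unrewarded).
#'
#' @param study A validated study table.
#' @param option 0-based option id.
#' @return A tibble with `participant_id`, `block_id`, `trial_index`, `y`,
#'   `Ct`, `Rt` and the block's partner noise condition.
#' @export
build_optionwise_design <- function(study, option) {
  option <- check_option(option)
  obs <- study[study$phase == "observational", ]
  if (nrow(obs) == 0L) stop("no observational trials")
  tibble::tibble(
    participant_id = obs$participant_id, block_id = obs$block_id,
    trial_index = obs$trial_index,
    y = as.integer(obs$participant_choice == option),
    Ct = ifelse(obs$partner_choice == option, 1, -1),
    Rt = ifelse(obs$partner_reward == 0, 0,
                ifelse(obs$partner_choice == option, 1, -1)),
    noise = obs$partner_noise)
}

#' Inverse-variance weighted pooling of coefficients
#'
#' Combines parallel estimates of the same effect (one per option-wise
#' model) with weights `1 / se^2`; the pooled standard error is
#' `sqrt(1 / sum(weights))`.
#'
#' @param estimates Numeric vector of coefficients.
#' @param ses Their standard errors (all `> 0`).
#' @return A list with `estimate` and `se`.
#' @export
pool_effects <- function(estimates, ses) {
  stopifnot(length(estimates) == length(ses))
  if (any(!is.finite(ses)) || any(ses <= 0)) {
    stop("standard errors must be positive and finite")
  }
  w <- 1 / ses^2
  list(estimate = sum(w * estimates) / sum(w), se = sqrt(1 / sum(w)))
}

#' Option-wise learning-style GLMMs with pooled effects
#'
#' Fits one mixed-effects logistic regression per option and pools each
#' fixed effect across the three models by inverse-variance weighting.
#' With `moderator = "P"` the models are
#' `y ~ (Ct + Rt) * P + (1 + Ct + Rt | participant)`, where `P` is the
#' participant's (uncentred) proportion of blocks selecting the high-noise
#' partner.  With `moderator = "D"` the models are
#' `y ~ (Ct + Rt) * D + (1 + (Ct + Rt) * D | participant)`, where `D` is
#' +1 for a high-noise and -1 for a low-noise block, and the data are
#' restricted to participants who selected both partner types at least
#' once.
#'
#' @param study A validated study table.
#' @param moderator `"P"` (between-participant preference) or `"D"`
#'   (within-participant noise level).
#' @param nAGQ Passed to [fit_mixed_logistic()].
#' @return A list with `fits` (per-option term tables), `pooled` (tibble
#'   of pooled estimates and SEs per term) and `n_participants`.
#' @export
optionwise_glmm <- function(study, moderator = c("P", "D"), nAGQ = 1L) {
  moderator <- match.arg(moderator)
  if (moderator == "P") {
    mod <- high_noise_preference(study)
    fixed <- c("Ct", "Rt", "P", "Ct:P", "Rt:P")
    random <- c("Ct", "Rt")
  } else {
    sel <- study_selections(study)
    both <- stats::aggregate(
      list(n_kind = sel$selected_partner),
      by = list(participant_id = sel$participant_id),
      FUN = function(x) length(unique(x)))
    keep <- both$participant_id[both$n_kind == 2L]
    if (length(keep) < 2L) {
      stop("fewer than 2 participants selected both partner types")
    }
    study <- study[study$participant_id %in% keep, ]
    fixed <- c("Ct", "Rt", "D", "Ct:D", "Rt:D")
    random <- c("Ct", "Rt", "D", "Ct:D", "Rt:D")
  }
  fits <- lapply(0:2, function(opt) {
    d <- build_optionwise_design(study, opt)
    if (moderator == "P") {
      d <- tibble::as_tibble(merge(as.data.frame(d),
                                   as.data.frame(mod),
                                   by = "participant_id"))
      names(d)[names(d) == "pref_high"] <- "P"
    } else {
      d$D <- ifelse(d$noise == "high", 1, -1)
    }
    fit_mixed_logistic(d, outcome = "y", fixed = fixed, random = random,
                       nAGQ = nAGQ)
  })
  terms <- fits[[1]]$terms$term
  pooled <- dplyr::bind_rows(lapply(terms, function(tm) {
    est <- vapply(fits, function(f)
      f$terms$estimate[f$terms$term == tm], numeric(1))
    se <- vapply(fits, function(f)
      f$terms$se[f$terms$term == tm], numeric(1))
    p <- pool_effects(est, se)
    tibble::tibble(term = tm, estimate = p$estimate, se = p$se,
                   pooled = TRUE)
  }))
  list(fits = lapply(fits, `[[`, "terms"), models = fits, pooled = pooled,
       n_participants = length(unique(study$participant_id)))
}

#' Simple slopes of a moderated effect
#'
#' Evaluates the marginal effect of a predictor at stated moderator
#' levels: `slope(m) = main + interaction * m`, with the standard error
#' from the coefficient covariance matrix.
#'
#' @param fit A fitted model object (`glmer` or `glm`) containing the main
#'   and interaction terms.
#' @param main Name of the main-effect coefficient.
#' @param interaction Name of the interaction coefficient.
#' @param at Numeric vector of moderator values.
#' @return A tibble with `at`, `estimate`, `se`.
#' @export
marginal_effects <- function(fit, main, interaction, at) {
  b <- if (inherits(fit, "merMod")) lme4::fixef(fit) else stats::coef(fit)
  V <- as.matrix(stats::vcov(fit))
  if (!interaction %in% names(b)) {
    flip <- paste(rev(strsplit(interaction, ":")[[1]]), collapse = ":")
    if (flip %in% names(b)) interaction <- flip else
      stop("interaction term ", interaction, " not in the model")
  }
  est <- b[[main]] + at * b[[interaction]]
  se <- sqrt(V[main, main] + at^2 * V[interaction, interaction] +
               2 * at * V[main, interaction])
  tibble::tibble(at = at, estimate = est, se = se)
}

#' Cohen's d for a two-group contrast
#'
#' Standardised mean difference `(mean_a - mean_b) / s_pooled` with the
#' pooled standard deviation
#' `sqrt(((n_a - 1) s_a^2 + (n_b - 1) s_b^2) / (n_a + n_b - 2))`.
#'
#' @param a,b Numeric vectors (each of length `>= 2`).
#' @return The effect size.
#' @export
cohens_d <- function(a, b) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  sp <- sqrt(((length(a) - 1) * stats::var(a) +
                (length(b) - 1) * stats::var(b)) /
               (length(a) + length(b) - 2))
  if (sp == 0) stop("zero pooled standard deviation")
  (mean(a) - mean(b)) / sp
}

#' Bootstrap power analysis for the selection model
#'
#' Simulates partner selections from a fitted Model 1 (fixed effects plus
#' by-participant random effects drawn from the estimated covariance),
#' refits the model, and records how often the noise-level coefficient is
#' significant at level `alpha` (two-tailed t-test, df = number of
#' participants).  Power is the significant fraction over `n_boot`
#' replicates, per candidate sample size.
#'
#' @param fit Result of [fit_mixed_logistic()] for Model 1.
#' @param n_values Candidate participant counts.
#' @param n_boot Bootstrap replicates per sample size.
#' @param n_blocks Blocks per simulated participant.
#' @param alpha Significance level.
#' @param seed Optional integer seed for the simulation.
#' @return A tibble with `n` and `power`.
#' @export
power_bootstrap <- function(fit, n_values, n_boot = 100L, n_blocks = 4L,
                            alpha = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (fit$method == "glmer") {
    b <- lme4::fixef(fit$fit)
    vc <- lme4::VarCorr(fit$fit)$participant_id
    Sigma <- as.matrix(vc[seq_along(b), seq_along(b)])
  } else {
    b <- stats::coef(fit$fit)
    Sigma <- matrix(0, length(b), length(b))
  }
  ch <- tryCatch(chol(Sigma), error = function(e)
    chol(Sigma + diag(1e-8, nrow(Sigma))))
  out <- lapply(n_values, function(n) {
    sig <- logical(n_boot)
    for (r in seq_len(n_boot)) {
      u <- matrix(stats::rnorm(n * length(b)), n) %*% ch
      sim <- do.call(rbind, lapply(seq_len(n), function(i) {
        X1 <- ifelse(stats::runif(n_blocks) < 0.5, 1, -1)
        eta <- (b[1] + u[i, 1]) + (b[2] + u[i, 2]) * X1
        data.frame(participant_id = i, Y = as.integer(
          stats::runif(n_blocks) < stats::plogis(eta)), X1 = X1)
      }))
      ref <- fit_mixed_logistic(sim, outcome = "Y", fixed = "X1")
      p <- ref$terms$p[ref$terms$term == "X1"]
      sig[r] <- is.finite(p) && p < alpha
    }
    tibble::tibble(n = n, power = mean(sig))
  })
  dplyr::bind_rows(out)
}

#' One-sample t-test of accuracy against chance
#'
#' Two-tailed one-sample t-test of per-participant proportions of correct
#' choices against the three-option chance level 1/3.
#'
#' @param proportions Per-participant proportions correct.
#' @param chance Chance level.
#' @return A list with `t`, `df`, `p`, and the `mean` proportion.
#' @export
ttest_vs_chance <- function(proportions, chance = 1 / 3) {
  stopifnot(length(proportions) >= 2L)
  if (stats::sd(proportions) == 0) {
    # degenerate sample: every proportion identical; at chance the
    # statistic is 0 by convention, away from chance it is unbounded
    t <- if (proportions[1] == chance) 0 else
      sign(proportions[1] - chance) * Inf
    return(list(t = t, df = length(proportions) - 1L,
                p = if (t == 0) 1 else 0, mean = proportions[1]))
  }
  tt <- stats::t.test(proportions, mu = chance)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean = mean(proportions))
}
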