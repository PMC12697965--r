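#' Raw-to-natural parameter transforms
#'
#' Individual parameters are sampled on an unconstrained raw scale and
#' transformed to their domains: unit-interval parameters (learning rates,
#' imitation weight, information-bonus weight) by the logistic function,
#' strictly positive parameters (inverse temperature) by the exponential.
#'
#' @param x Raw-scale value(s).
#' @param role `"unit"` or `"positive"`.
#' @return Natural-scale value(s).
#' @export
to_natural <- function(x, role = c("unit", "positive")) {
  role <- match.arg(role)
  switch(role, unit = stats::plogis(x), positive = exp(x))
}

#' @rdname to_natural
#' @export
to_raw <- function(x, role = c("unit", "positive")) {
  role <- match.arg(role)
  switch(role, unit = stats::qlogis(x), positive = log(x))
}

model_roles <- function(kind) {
  switch(kind,
    full = c(alpha_v = "unit", alpha_a = "unit", w_a = "unit",
             beta = "positive"),
    action_only = c(alpha_a = "unit", beta = "positive"),
    reward_only = c(alpha_v = "unit", beta = "positive"),
    info_bonus = c(alpha = "unit", beta = "positive", kappa = "unit")
  )
}

# Map a named natural-parameter vector of a given kind to the 4-slot
# (alpha_v, alpha_a, w_a, beta) layout the C++ likelihood expects; unused
# slots are inert for that kind.
full_slot <- function(nat, kind) {
  switch(kind,
    full = c(nat[["alpha_v"]], nat[["alpha_a"]], nat[["w_a"]],
             nat[["beta"]]),
    action_only = c(0, nat[["alpha_a"]], 1, nat[["beta"]]),
    reward_only = c(nat[["alpha_v"]], 0, 0, nat[["beta"]])
  )
}

obs_data_by_participant <- function(study, phase = "observational") {
  trials <- study[study$phase %in% phase, ]
  if (nrow(trials) == 0L) stop("no trials in phase ",
                               paste(phase, collapse = "/"))
  trials <- trials[order(trials$participant_id, trials$block_id,
                         trials$trial_index), ]
  ids <- unique(trials$participant_id)
  dat <- lapply(ids, function(id) {
    prep_obs_trials(trials[trials$participant_id == id, ])
  })
  names(dat) <- ids
  list(ids = ids, data = dat)
}

log_half_cauchy <- function(sigma, scale = 3) {
  ifelse(sigma > 0,
         log(2) + stats::dcauchy(sigma, 0, scale, log = TRUE), -Inf)
}

#' Hierarchical log joint density
#'
#' The unnormalised log posterior of the hierarchical model: the
#' observational-choice log-likelihood of every participant at the
#' natural-scale transform of their raw parameters, plus Normal population
#' densities of the raw parameters given the population means and
#' standard deviations, plus the hyperpriors (means: standard normal;
#' standard deviations: half-Cauchy with scale 3).
#'
#' @param study A study table with observational trials.
#' @param kind Model kind.
#' @param theta_raw Matrix of raw parameters, participants x parameters
#'   (columns in the order of `model_roles(kind)`).
#' @param mu Population means (one per parameter).
#' @param sigma Population standard deviations (one per parameter).
#' @return The scalar log joint density.
#' @export
log_joint <- function(study, kind, theta_raw, mu, sigma) {
  kind <- match.arg(kind, model_kinds())
  roles <- model_roles(kind)
  k <- length(roles)
  theta_raw <- matrix(theta_raw, ncol = k)
  stopifnot(length(mu) == k, length(sigma) == k)
  dat <- obs_data_by_participant(study)
  if (nrow(theta_raw) != length(dat$ids)) {
    stop("theta_raw has ", nrow(theta_raw), " rows but the study has ",
         length(dat$ids), " participants")
  }
  ll <- 0
  for (i in seq_along(dat$ids)) {
    nat <- stats::setNames(
      mapply(to_natural, theta_raw[i, ], roles), names(roles))
    p <- full_slot(nat, kind)
    d <- dat$data[[i]]
    li <- sum(obs_loglik_cpp(d$pc, d$pr, d$yc, d$starts, p[1], p[2], p[3],
                             p[4], kind_code(kind)))
    if (!is.finite(li)) stop("non-finite likelihood for participant ",
                             dat$ids[i])
    ll <- ll + li
  }
  pop <- sum(stats::dnorm(theta_raw, rep(mu, each = nrow(theta_raw)),
                          rep(sigma, each = nrow(theta_raw)), log = TRUE))
  hyper <- sum(stats::dnorm(mu, 0, 1, log = TRUE)) +
    sum(log_half_cauchy(sigma))
  if (!is.finite(pop)) stop("non-finite population density")
  if (!is.finite(hyper)) stop("non-finite hyperprior density")
  ll + pop + hyper
}

# Univariate stepping-out slice sampler (Neal 2003) for the conditional of
# one population log-sd.
slice_sample1 <- function(x0, logf, w = 1, max_steps = 50L) {
  y <- logf(x0) - stats::rexp(1)
  l <- x0 - stats::runif(1) * w
  r <- l + w
  steps <- 0L
  while (logf(l) > y && steps < max_steps) {
    l <- l - w
    steps <- steps + 1L
  }
  steps <- 0L
  while (logf(r) > y && steps < max_steps) {
    r <- r + w
    steps <- steps + 1L
  }
  repeat {
    x1 <- stats::runif(1, l, r)
    if (logf(x1) >= y) return(x1)
    if (x1 < x0) l <- x1 else r <- x1
  }
}

natural_matrix <- function(theta, roles) {
  nat <- theta
  for (j in seq_along(roles)) {
    nat[, j] <- to_natural(theta[, j], roles[j])
  }
  nat
}

# Generic hierarchical adaptive Metropolis-within-Gibbs sampler.
#
# loglik_batch(nat) takes the natural-scale parameter matrix (subjects in
# rows) and returns every subject's data log-likelihood, so one C++ call
# serves a whole cross-subject Metropolis sweep.  Individual raw
# parameters get coordinate-wise random-walk Metropolis updates
# (per-subject per-parameter step sizes adapted during warmup toward
# ~35% acceptance) plus joint random-walk proposals whose per-subject
# covariance is learned from the warmup history (Haario-style adaptive
# Metropolis), which handles correlated within-subject posteriors.
# Population means are conjugate-Gibbs updates (normal likelihood,
# standard-normal prior); population log-sds are slice sampled under the
# half-Cauchy(0, 3) prior.
hier_mcmc <- function(loglik_batch, n_subj, roles, chains = 4L,
                      warmup = 1000L, iter = 1000L, seed = 1L,
                      sweeps = 3L, joint_props = 4L, prior_props = 2L) {
  k <- length(roles)
  par_names <- names(roles)
  draws <- array(NA_real_,
                 dim = c(chains, iter, n_subj * k + 2L * k))
  dimnames(draws) <- list(NULL, NULL, c(
    paste0(rep(par_names, each = n_subj), "[",
           rep(seq_len(n_subj), k), "]"),
    paste0("mu_", par_names), paste0("sigma_", par_names)))
  cov_from <- max(25L, warmup %/% 4L)     # start of covariance learning
  cov_ready <- max(50L, warmup %/% 2L)    # first iteration joint moves run

  # Per-subject penalised-likelihood mode, used (jittered) as the chain
  # initialisation so short chains spend no time on the initial transient.
  set.seed(as.integer((as.numeric(seed) + 104695) %% 2147483647))
  map <- matrix(0, n_subj, k)
  for (i in seq_len(n_subj)) {
    obj <- function(v) {
      th <- map
      th[i, ] <- v
      -(loglik_batch(natural_matrix(th, roles))[i] +
          sum(stats::dnorm(v, 0, 1.5, log = TRUE)))
    }
    map[i, ] <- stats::optim(rep(0, k), obj,
                             control = list(maxit = 200))$par
  }

  for (ch in seq_len(chains)) {
    set.seed(as.integer((as.numeric(seed) + 7919 * ch) %% 2147483647))
    theta <- map + matrix(stats::rnorm(n_subj * k, 0, 0.3), n_subj, k)
    mu <- colMeans(map)
    sigma <- pmax(apply(map, 2, stats::sd), 0.5)
    step <- matrix(0.5, n_subj, k)
    acc <- matrix(0, n_subj, k)
    nat <- natural_matrix(theta, roles)
    cur_ll <- loglik_batch(nat)
    # Welford accumulators for the per-subject warmup covariance
    w_n <- 0L
    w_mean <- matrix(0, n_subj, k)
    w_cov <- array(0, c(n_subj, k, k))
    chol_L <- NULL
    lambda <- rep(1, n_subj)
    jacc <- rep(0, n_subj)
    jtot <- 0L

    update_chol <- function() {
      lapply(seq_len(n_subj), function(i) {
        S <- w_cov[i, , ] / max(w_n - 1L, 1L)
        S <- 2.38^2 / k * S + diag(1e-6, k)
        chol(S)
      })
    }

    for (it in seq_len(warmup + iter)) {
      for (sw in seq_len(sweeps)) {
        for (j in seq_len(k)) {
          prop_j <- theta[, j] + stats::rnorm(n_subj, 0, step[, j])
          nat_prop <- nat
          nat_prop[, j] <- to_natural(prop_j, roles[j])
          ll_new <- loglik_batch(nat_prop)
          lp <- ll_new - cur_ll +
            stats::dnorm(prop_j, mu[j], sigma[j], log = TRUE) -
            stats::dnorm(theta[, j], mu[j], sigma[j], log = TRUE)
          take <- is.finite(lp) & log(stats::runif(n_subj)) < lp
          if (any(take)) {
            theta[take, j] <- prop_j[take]
            nat[take, j] <- nat_prop[take, j]
            cur_ll[take] <- ll_new[take]
            acc[take, j] <- acc[take, j] + 1
          }
        }
      }
      if (!is.null(chol_L)) {
        for (jp in seq_len(joint_props)) {
          prop <- theta
          for (i in seq_len(n_subj)) {
            prop[i, ] <- theta[i, ] +
              sqrt(lambda[i]) * drop(crossprod(chol_L[[i]],
                                               stats::rnorm(k)))
          }
          nat_prop <- natural_matrix(prop, roles)
          ll_new <- loglik_batch(nat_prop)
          pr_diff <- rowSums(
            stats::dnorm(prop, rep(mu, each = n_subj),
                         rep(sigma, each = n_subj), log = TRUE) -
              stats::dnorm(theta, rep(mu, each = n_subj),
                           rep(sigma, each = n_subj), log = TRUE))
          lp <- ll_new - cur_ll + pr_diff
          take <- is.finite(lp) & log(stats::runif(n_subj)) < lp
          if (any(take)) {
            theta[take, ] <- prop[take, , drop = FALSE]
            nat[take, ] <- nat_prop[take, , drop = FALSE]
            cur_ll[take] <- ll_new[take]
            jacc[take] <- jacc[take] + 1
          }
          jtot <- jtot + 1L
        }
      }
      # independence proposals from the population distribution: the
      # population density cancels against the proposal, so acceptance
      # depends on the likelihood alone.  These carry weakly identified
      # subjects (near-flat likelihoods) across ridges in one move.
      for (pp in seq_len(prior_props)) {
        prop <- matrix(stats::rnorm(n_subj * k, rep(mu, each = n_subj),
                                    rep(sigma, each = n_subj)), n_subj, k)
        nat_prop <- natural_matrix(prop, roles)
        ll_new <- loglik_batch(nat_prop)
        lp <- ll_new - cur_ll
        take <- is.finite(lp) & log(stats::runif(n_subj)) < lp
        if (any(take)) {
          theta[take, ] <- prop[take, , drop = FALSE]
          nat[take, ] <- nat_prop[take, , drop = FALSE]
          cur_ll[take] <- ll_new[take]
        }
      }
      # population means: conjugate normal given sigma and theta
      for (j in seq_len(k)) {
        prec <- n_subj / sigma[j]^2 + 1
        m <- sum(theta[, j]) / sigma[j]^2 / prec
        mu[j] <- stats::rnorm(1, m, sqrt(1 / prec))
      }
      # population sds: slice sample log-sigma
      for (j in seq_len(k)) {
        tj <- theta[, j]
        mj <- mu[j]
        logf <- function(ls) {
          s <- exp(ls)
          sum(stats::dnorm(tj, mj, s, log = TRUE)) +
            log_half_cauchy(s) + ls  # Jacobian of the log transform
        }
        sigma[j] <- exp(slice_sample1(log(sigma[j]), logf))
      }
      if (it <= warmup) {
        if (it >= cov_from) {
          w_n <- w_n + 1L
          delta <- theta - w_mean
          w_mean <- w_mean + delta / w_n
          delta2 <- theta - w_mean
          for (i in seq_len(n_subj)) {
            w_cov[i, , ] <- w_cov[i, , ] + tcrossprod(delta[i, ],
                                                      delta2[i, ])
          }
        }
        if (it %% 25L == 0L) {
          rate <- acc / (25 * sweeps)
          step <- step * exp(rate - 0.35)
          step <- pmin(pmax(step, 1e-3), 10)
          acc[] <- 0
          if (it >= cov_ready && w_n > 2L * k) {
            chol_L <- update_chol()
            if (jtot > 0L) {
              lambda <- pmin(pmax(lambda * exp(jacc / jtot - 0.25),
                                  1e-3), 100)
              jacc[] <- 0
              jtot <- 0L
            }
          }
        }
      }
      if (it > warmup) {
        draws[ch, it - warmup, ] <- c(theta, mu, sigma)
      }
    }
  }
  draws
}

#' Split R-hat convergence diagnostic
#'
#' @param x Matrix of draws, chains in columns (iterations x chains), for
#'   one scalar parameter.
#' @return The split-chain potential scale reduction factor.
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x) %/% 2L
  halves <- cbind(x[seq_len(n), , drop = FALSE],
                  x[n + seq_len(n), , drop = FALSE])
  m <- ncol(halves)
  means <- colMeans(halves)
  vars <- apply(halves, 2, stats::var)
  b <- n * stats::var(means)
  w <- mean(vars)
  if (w == 0) return(1)
  sqrt(((n - 1) / n * w + b / n) / w)
}

# Crude effective sample size from pooled-chain autocorrelations
# (initial monotone positive sequence).
ess_basic <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x) * ncol(x)
  rho <- rowMeans(vapply(seq_len(ncol(x)), function(ch) {
    a <- stats::acf(x[, ch], lag.max = min(nrow(x) - 1L, 100L),
                    plot = FALSE)$acf[-1L]
    as.numeric(a)
  }, numeric(min(nrow(x) - 1L, 100L))))
  s <- 0
  for (t in seq_along(rho)) {
    if (rho[t] < 0) break
    s <- s + rho[t]
  }
  n / (1 + 2 * s)
}

#' Widely-applicable Akaike information criterion
#'
#' Computed from a pointwise log-likelihood matrix with posterior draws in
#' rows and observations (trials) in columns: the log pointwise predictive
#' density uses a log-sum-exp over draws, the effective number of
#' parameters is the summed across-draw variance, and
#' `waic = -2 * (lppd - p_waic)`.
#'
#' @param ll Matrix of pointwise log-likelihoods (draws x observations).
#' @return A list with `waic`, `lppd` and `p_waic`.
#' @export
waic <- function(ll) {
  ll <- as.matrix(ll)
  if (nrow(ll) < 2L) stop("WAIC needs at least 2 posterior draws")
  mx <- apply(ll, 2, max)
  lppd <- sum(log(colMeans(exp(sweep(ll, 2, mx)))) + mx)
  p_waic <- sum(apply(ll, 2, stats::var))
  list(waic = -2 * (lppd - p_waic), lppd = lppd, p_waic = p_waic)
}

#' Fit an observational-learning model hierarchically
#'
#' Samples the joint posterior of all participants' raw parameters and the
#' population means and standard deviations with an adaptive
#' Metropolis-within-Gibbs scheme: random-walk Metropolis on each
#' participant's raw parameters (step sizes adapted during warmup),
#' conjugate Gibbs updates of the population means, and slice sampling of
#' the population standard deviations under their half-Cauchy priors.
#'
#' @param study A study table containing observational trials.
#' @param kind Model kind (see [model_kinds()]).
#' @param chains Number of independent chains.
#' @param warmup Warmup (adaptation) iterations per chain, discarded.
#' @param iter Retained sampling iterations per chain.
#' @param seed Integer seed; the sampler is deterministic given
#'   (data, settings, seed).
#' @param phase Study phase(s) whose trials are fitted.
#' @return An object of class `oblearn_fit`: posterior draws, natural-scale
#'   posterior-mean parameters per participant, the pointwise
#'   log-likelihood matrix (draws x trials), WAIC, and diagnostics
#'   (split R-hat and effective sample size per scalar parameter).  A
#'   split R-hat above 1.05 on any parameter is recorded as a warning in
#'   the result, not an error.
#' @export
fit_hierarchical <- function(study, kind = "full", chains = 4L,
                             warmup = 1000L, iter = 1000L, seed = 1L,
                             phase = "observational") {
  kind <- match.arg(kind, model_kinds())
  roles <- model_roles(kind)
  dat <- obs_data_by_participant(study, phase)
  n_subj <- length(dat$ids)
  code <- kind_code(kind)

  lens <- vapply(dat$data, function(d) length(d$pc), integer(1))
  subj_start <- c(0L, cumsum(lens))
  cat_pc <- unlist(lapply(dat$data, `[[`, "pc"), use.names = FALSE)
  cat_pr <- unlist(lapply(dat$data, `[[`, "pr"), use.names = FALSE)
  cat_yc <- unlist(lapply(dat$data, `[[`, "yc"), use.names = FALSE)
  cat_starts <- unlist(lapply(seq_len(n_subj), function(i)
    dat$data[[i]]$starts + subj_start[i]), use.names = FALSE)

  slot_mat <- function(nat) {
    switch(kind,
      full = nat,
      action_only = cbind(0, nat[, 1], 1, nat[, 2]),
      reward_only = cbind(nat[, 1], 0, 0, nat[, 2]))
  }
  loglik_batch <- function(nat) {
    obs_loglik_batch_cpp(cat_pc, cat_pr, cat_yc, cat_starts, subj_start,
                         slot_mat(nat), code)
  }
  draws <- hier_mcmc(loglik_batch, n_subj, roles, chains, warmup, iter,
                     seed)
  finalize_fit(draws, dat, kind, roles, chains, iter,
               pointwise_fun = function(d, nat_mat) {
                 slots <- t(apply(nat_mat, 1, function(r)
                   full_slot(as.list(r), kind)))
                 obs_loglik_draws_cpp(d$pc, d$pr, d$yc, d$starts, slots,
                                      code)
               })
}

# Shared post-processing: posterior means, pointwise log-likelihood,
# WAIC, diagnostics.
finalize_fit <- function(draws, dat, kind, roles, chains, iter,
                         pointwise_fun) {
  n_subj <- length(dat$ids)
  k <- length(roles)
  par_names <- names(roles)
  flat <- matrix(draws, nrow = chains * iter,
                 dimnames = list(NULL, dimnames(draws)[[3]]))

  nat_means <- matrix(NA_real_, n_subj, k,
                      dimnames = list(NULL, par_names))
  pointwise <- NULL
  for (i in seq_len(n_subj)) {
    raw_i <- flat[, paste0(par_names, "[", i, "]"), drop = FALSE]
    nat_i <- vapply(seq_len(k), function(j)
      to_natural(raw_i[, j], roles[j]), numeric(nrow(raw_i)))
    colnames(nat_i) <- par_names
    nat_means[i, ] <- colMeans(nat_i)
    pointwise <- cbind(pointwise, pointwise_fun(dat$data[[i]], nat_i))
  }
  w <- waic(pointwise)

  diag_tab <- tibble::tibble(
    parameter = dimnames(draws)[[3]],
    rhat = vapply(seq_len(dim(draws)[3]), function(p)
      split_rhat(t(draws[, , p])), numeric(1)),
    ess = vapply(seq_len(dim(draws)[3]), function(p)
      ess_basic(t(draws[, , p])), numeric(1)))
  warn <- character()
  if (any(diag_tab$rhat > 1.05, na.rm = TRUE)) {
    warn <- sprintf("split R-hat > 1.05 for %d parameter(s); max = %.3f",
                    sum(diag_tab$rhat > 1.05, na.rm = TRUE),
                    max(diag_tab$rhat, na.rm = TRUE))
  }
  structure(list(kind = kind, participants = dat$ids, draws = draws,
                 posterior_means = tibble::as_tibble(
                   cbind(tibble::tibble(participant_id = dat$ids),
                         as.data.frame(nat_means))),
                 pointwise = pointwise, waic = w, diagnostics = diag_tab,
                 warnings = warn),
            class = "oblearn_fit")
}

#' @export
print.oblearn_fit <- function(x, ...) {
  cat("<oblearn_fit>", x$kind, "model,", length(x$participants),
      "participants\n")
  cat(sprintf("  WAIC %.1f (lppd %.1f, p_waic %.1f)\n", x$waic$waic,
              x$waic$lppd, x$waic$p_waic))
  cat(sprintf("  max split R-hat %.3f\n", max(x$diagnostics$rhat,
                                              na.rm = TRUE)))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Compare fitted models by WAIC
#'
#' @param ... Named `oblearn_fit` objects.
#' @return A tibble sorted by WAIC (best first).
#' @export
compare_waic <- function(...) {
  fits <- list(...)
  if (length(fits) == 1L && is.list(fits[[1]]) &&
      !inherits(fits[[1]], "oblearn_fit")) fits <- fits[[1]]
  tab <- tibble::tibble(
    model = vapply(fits, function(f) f$kind, character(1)),
    waic = vapply(fits, function(f) f$waic$waic, numeric(1)),
    lppd = vapply(fits, function(f) f$waic$lppd, numeric(1)),
    p_waic = vapply(fits, function(f) f$waic$p_waic, numeric(1)))
  tab[order(tab$waic), ]
}
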