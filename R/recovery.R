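rep_seed <- function(seed, rep, offset = 0L) {
  as.integer((as.numeric(seed) + 104729 * rep + 13 * offset) %% 2147483647)
}

#' Model recovery: the WAIC confusion matrix
#'
#' For each replicate and each generating model, a full synthetic study is
#' generated from that model, all three candidate models are fitted
#' hierarchically, and the winner is the model with the lowest WAIC.  The
#' confusion matrix tabulates, per generating model (rows), the proportion
#' of replicates won by each candidate (columns); a matrix close to the
#' identity indicates that the models are mutually identifiable.
#'
#' @param design A [study_design()].
#' @param n_reps Replicates per generating model.
#' @param chains,warmup,iter MCMC settings passed to
#'   [fit_hierarchical()].
#' @param seed Master seed; replicate seeds are derived deterministically.
#' @return A list of class `confusion_matrix`: `matrix` (3 x 3 row-wise
#'   proportions), `counts`, and `n_failed` fits (excluded).
#' @export
model_recovery <- function(design, n_reps = 40L, chains = 4L,
                           warmup = 200L, iter = 200L, seed = 1L) {
  stopifnot(n_reps >= 1L)
  kinds <- model_kinds()
  counts <- matrix(0L, 3, 3, dimnames = list(kinds, kinds))
  n_failed <- 0L
  for (rep in seq_len(n_reps)) {
    for (g in seq_along(kinds)) {
      sim <- generate_study(design, kinds[g],
                            seed = rep_seed(seed, rep, g))
      waics <- vapply(seq_along(kinds), function(f) {
        tryCatch(
          fit_hierarchical(sim$study, kinds[f], chains, warmup, iter,
                           seed = rep_seed(seed, rep, 3L + f))$waic$waic,
          error = function(e) NA_real_)
      }, numeric(1))
      if (any(is.na(waics))) {
        n_failed <- n_failed + 1L
      } else {
        counts[g, which.min(waics)] <- counts[g, which.min(waics)] + 1L
      }
    }
  }
  prop <- counts / pmax(rowSums(counts), 1L)
  structure(list(matrix = prop, counts = counts, n_failed = n_failed),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> rows = generating model, cols = WAIC winner\n")
  print(round(x$matrix, 3))
  if (x$n_failed > 0L) cat("  failed fits excluded:", x$n_failed, "\n")
  invisible(x)
}

#' Parameter recovery for the Full model
#'
#' Per replicate: generate a synthetic study from the Full model, refit
#' it, and correlate posterior-mean parameter estimates with the
#' generating values across participants (Pearson).  Signed errors
#' (estimated minus true) are kept per participant, along with each
#' simulated participant's count of high-noise blocks so that recovery can
#' be stratified by partner preference afterwards.
#'
#' @inheritParams model_recovery
#' @return A list of class `recovery_result`: `correlations` (tibble:
#'   rep, parameter, r), `errors` (tibble: rep, participant, parameter,
#'   true, estimated, error, n_high_blocks) and `n_failed`.
#' @export
parameter_recovery <- function(design, n_reps = 40L, chains = 4L,
                               warmup = 200L, iter = 200L, seed = 1L) {
  pars <- c("alpha_v", "alpha_a", "w_a", "beta")
  cors <- list()
  errs <- list()
  n_failed <- 0L
  for (rep in seq_len(n_reps)) {
    sim <- generate_study(design, "full", seed = rep_seed(seed, rep))
    fit <- tryCatch(
      fit_hierarchical(sim$study, "full", chains, warmup, iter,
                       seed = rep_seed(seed, rep, 7L)),
      error = function(e) NULL)
    if (is.null(fit)) {
      n_failed <- n_failed + 1L
      next
    }
    est <- fit$posterior_means
    truth <- sim$truth
    block_cols <- grep("^block_", names(truth), value = TRUE)
    n_high <- rowSums(truth[, block_cols, drop = FALSE] == "high")
    m <- merge(as.data.frame(truth), as.data.frame(est),
               by = "participant_id", suffixes = c("_true", "_est"))
    for (p in pars) {
      cors[[length(cors) + 1L]] <- tibble::tibble(
        rep = rep, parameter = p,
        r = stats::cor(m[[paste0(p, "_true")]], m[[paste0(p, "_est")]]))
      errs[[length(errs) + 1L]] <- tibble::tibble(
        rep = rep, participant_id = m$participant_id, parameter = p,
        true = m[[paste0(p, "_true")]],
        estimated = m[[paste0(p, "_est")]],
        error = m[[paste0(p, "_est")]] - m[[paste0(p, "_true")]],
        n_high_blocks = n_high[match(m$participant_id,
                                     truth$participant_id)],
        n_blocks = length(block_cols))
    }
  }
  structure(list(correlations = dplyr::bind_rows(cors),
                 errors = dplyr::bind_rows(errs), n_failed = n_failed),
            class = "recovery_result")
}

#' Stratify parameter recovery by partner preference
#'
#' Splits simulated participants into a high-noise-preference group (more
#' than half of their blocks with the high-noise partner) and a
#' low-noise-preference group (more than half low-noise); participants
#' with an exact split are discarded.  With the 4-block design this is the
#' "more than twice" rule.  Correlations and mean signed errors are then
#' computed per group and parameter; a group with fewer than 3
#' participants in a replicate has its correlation omitted with a
#' warning.
#'
#' @param result A [parameter_recovery()] result.
#' @return A tibble with `rep`, `group`, `parameter`, `n`, `r` and
#'   `mean_error`.
#' @export
stratified_recovery <- function(result) {
  e <- result$errors
  half <- e$n_blocks / 2
  e$group <- ifelse(e$n_high_blocks > half, "high_pref",
                    ifelse(e$n_high_blocks < half, "low_pref", NA))
  e <- e[!is.na(e$group), ]
  groups <- split(e, list(e$rep, e$group, e$parameter), drop = TRUE)
  out <- dplyr::bind_rows(lapply(groups, function(g) {
    r <- if (nrow(g) < 3L) {
      warning("group '", g$group[1L], "' in replicate ", g$rep[1L],
              " has fewer than 3 participants; correlation omitted")
      NA_real_
    } else {
      stats::cor(g$true, g$estimated)
    }
    tibble::tibble(rep = g$rep[1L], group = g$group[1L],
                   parameter = g$parameter[1L], n = nrow(g), r = r,
                   mean_error = mean(g$error))
  }))
  out[order(out$rep, out$group, out$parameter), ]
}
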