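default_config <- function() {
  list(
    seed = NULL,
    out_dir = "oblearn_run",
    design = list(n_participants = 74L, n_blocks = 4L, passive_trials = 30L,
                  observational_trials = 60L, practice_trials = 60L,
                  p_low_noise = 0.7, reward_probs = c(0.25, 0.50, 0.75)),
    fit = list(chains = 4L, warmup = 1000L, iter = 1000L),
    recovery = list(model_reps = 40L, parameter_reps = 40L,
                    chains = 4L, warmup = 200L, iter = 200L),
    regress = list(nAGQ = 1L),
    ppc = list(reps = 500L, refit_glmm = TRUE)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Read and validate a pipeline run configuration
#'
#' The run configuration is a single YAML file with one section per stage
#' (`design`, `fit`, `recovery`, `regress`, `ppc`) plus a mandatory master
#' `seed` and an `out_dir`.  Unspecified settings fall back to the
#' full-scale defaults (74 participants, 4 blocks, 4 chains of 1000+1000
#' iterations, 40 recovery replicates, 500 posterior predictive
#' replicates); a bundled `reduced.yaml` (see
#' `system.file("config", package = "oblearn")`) runs the whole pipeline
#' at desk scale.
#'
#' @param path Path to a YAML configuration file.
#' @return A validated configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- merge_config(default_config(), yaml::read_yaml(path))
  if (is.null(cfg$seed)) stop("configuration must set a master seed")
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

write_csv_artifact <- function(x, dir, name) {
  path <- file.path(dir, name)
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes, in order: synthetic-study generation; hierarchical fits of
#' the three observational-learning models with a WAIC comparison table;
#' model and parameter recovery; the practice-phase information-bonus fit
#' and partner metrics; the partner-selection and learning-style
#' regressions; and posterior predictive checks.  Every stage writes CSV
#' artifacts under the output directory, and a manifest with MD5 content
#' hashes is written last, so that two runs with the same configuration
#' and seed produce identical hashes.
#'
#' @param config A configuration list from [read_run_config()] or a path
#'   to a YAML file.
#' @param out_dir Output directory (overrides the configuration).
#' @return Invisibly, the manifest tibble (file, md5).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  if (is.null(config$seed)) stop("configuration must set a master seed")
  dir <- out_dir %||% config$out_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  design <- do.call(study_design, config$design)
  sim <- stage("simulate", {
    s <- generate_study(design, "full", seed = config$seed)
    files["study"] <- file.path(dir, "study.csv")
    write_study(s$study, files["study"])
    files["truth"] <- write_csv_artifact(s$truth, dir, "truth.csv")
    s
  })

  fits <- stage("fit", lapply(model_kinds(), function(k) {
    fit_hierarchical(sim$study, k, config$fit$chains, config$fit$warmup,
                     config$fit$iter, seed = rep_seed(config$seed, 1L,
                                                      kind_code(k)))
  }))
  names(fits) <- model_kinds()
  files["waic"] <- write_csv_artifact(compare_waic(fits), dir, "waic.csv")
  files["posterior_means"] <- write_csv_artifact(
    fits$full$posterior_means, dir, "posterior_means.csv")

  rec_cfg <- config$recovery
  conf <- stage("recover", model_recovery(
    design, rec_cfg$model_reps, rec_cfg$chains, rec_cfg$warmup,
    rec_cfg$iter, seed = rep_seed(config$seed, 2L)))
  files["confusion"] <- write_csv_artifact(
    as.data.frame(conf$matrix), dir, "confusion_matrix.csv")
  prec <- stage("recover", parameter_recovery(
    design, rec_cfg$parameter_reps, rec_cfg$chains, rec_cfg$warmup,
    rec_cfg$iter, seed = rep_seed(config$seed, 3L)))
  files["recovery"] <- write_csv_artifact(prec$correlations, dir,
                                          "parameter_recovery.csv")

  practice <- stage("metrics", fit_practice_model(
    sim$study, config$fit$chains, config$fit$warmup, config$fit$iter,
    seed = rep_seed(config$seed, 4L)))
  metrics <- stage("metrics", partner_metrics(sim$study, practice))
  files["metrics"] <- write_csv_artifact(metrics, dir, "metrics.csv")
  regs <- stage("metrics", selection_regressors(metrics))

  res <- stage("regress", {
    d1 <- build_selection_design(sim$study, "model1")
    d2 <- build_selection_design(sim$study, "model2")
    df <- build_selection_design(sim$study, "factors", regs)
    m1 <- fit_mixed_logistic(d1, fixed = "X1")
    m2 <- fit_mixed_logistic(d2, fixed = c("X1", "X2"))
    mf <- fit_mixed_logistic(df, fixed = c("z_performance",
                                           "z_predictability",
                                           "z_information_gain"))
    style <- optionwise_glmm(sim$study, "P", nAGQ = config$regress$nAGQ)
    fixed_tab <- function(analysis, terms) {
      cbind(analysis = analysis, as.data.frame(terms), pooled = FALSE)
    }
    style_tab <- as.data.frame(style$pooled)
    style_tab$stat <- NA_real_
    style_tab$df <- NA_integer_
    style_tab$p <- NA_real_
    style_tab$method <- "pooled"
    cols <- c("analysis", "term", "estimate", "se", "stat", "df", "p",
              "pooled", "method")
    rbind(fixed_tab("selection1", m1$terms)[, cols],
          fixed_tab("selection2", m2$terms)[, cols],
          fixed_tab("factors", mf$terms)[, cols],
          cbind(analysis = "style_between", style_tab)[, cols])
  })
  files["regressions"] <- write_csv_artifact(res, dir, "regressions.csv")

  ppc <- stage("ppc", run_ppc(fits$full, sim$study, config$ppc$reps,
                              seed = rep_seed(config$seed, 5L),
                              refit_glmm = isTRUE(config$ppc$refit_glmm),
                              nAGQ = config$regress$nAGQ))
  files["ppc_curve"] <- write_csv_artifact(
    data.frame(trial_index = seq_along(ppc$curve_mean) - 1L,
               mean = ppc$curve_mean, sd = ppc$curve_sd),
    dir, "ppc_curve.csv")
  if (!is.null(ppc$effect_summary)) {
    files["ppc_effects"] <- write_csv_artifact(ppc$effect_summary, dir,
                                               "ppc_effects.csv")
  }

  manifest <- tibble::tibble(
    file = basename(unname(files)),
    md5 = unname(tools::md5sum(unname(files))))
  write_csv_artifact(manifest, dir, "manifest.csv")
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
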