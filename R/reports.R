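# Pipeline stages writing survey-style report files (CSV/JSON/Markdown).
# Each stage is a plain function over the package's objects; a thin
# command-line front-end lives in inst/cli/bivmlogit.R.

.ensure_dir <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  invisible(dir)
}

.write_meta <- function(out_dir, seed = NULL, extra = list()) {
  meta <- c(list(
    package = "bivmlogit",
    version = as.character(utils::packageVersion("bivmlogit")),
    seed = seed), extra)
  jsonlite::write_json(meta, file.path(out_dir, "meta.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

.write_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write the descriptive report for an analysis table
#'
#' Produces the survey-style descriptive layer as files: the weighted
#' frequency distribution of the two outcomes, per-covariate weighted
#' cross-tabs with chi-square tests against each outcome, the joint 2x2
#' outcome table with its Woolf odds-ratio interval, per-covariate joint
#' risk profiles, and a combined Markdown report.
#'
#' @param table a `bivml_table`.
#' @param out_dir output directory (created if absent).
#' @param covariates covariate names for cross-tabs and risk profiles;
#'   defaults to every covariate declared in the table's schema.
#' @return invisibly, the named list of file paths written.
#' @export
run_describe <- function(table, out_dir,
                         covariates = names(.tab_schema(table))) {
  .ensure_dir(out_dir)
  cols <- .tab_cols(table)
  files <- list()

  freq <- do.call(rbind, lapply(c(cols$y1, cols$y2), function(v)
    cbind(variable = v, weighted_frequency(table, v))))
  files$outcome_frequencies <- .write_csv(
    freq, file.path(out_dir, "outcome_frequencies.csv"))

  xt_rows <- list()
  for (cv in covariates) for (oc in c(cols$y1, cols$y2)) {
    ct <- crosstab_chisq(table, cv, oc)
    xt_rows[[paste(cv, oc)]] <- data.frame(
      covariate = cv, outcome = oc, statistic = ct$statistic,
      df = ct$df, p_value = ct$p_value)
  }
  if (length(xt_rows))
    files$crosstab_tests <- .write_csv(
      do.call(rbind, xt_rows), file.path(out_dir, "crosstab_tests.csv"))

  jt <- joint_outcome_table(table)
  or <- if (!jt$degenerate) contingency_odds_ratio(jt) else
    list(or_hat = NA, ci_low = NA, ci_high = NA, level = 0.95)
  joint <- data.frame(
    cell = names(jt$counts), count = as.numeric(jt$counts),
    proportion = as.numeric(jt$proportions))
  files$joint_table <- .write_csv(joint,
                                  file.path(out_dir, "joint_table.csv"))
  jsonlite::write_json(
    list(counts = as.list(jt$counts), total = jt$total,
         proportions = as.list(jt$proportions),
         odds_ratio = or$or_hat,
         ci = c(or$ci_low, or$ci_high), level = or$level),
    file.path(out_dir, "joint_odds_ratio.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)

  if (length(covariates)) {
    prof <- do.call(rbind, lapply(covariates, function(cv)
      cbind(covariate = cv, joint_risk_profile(table, cv))))
    files$risk_profiles <- .write_csv(
      prof, file.path(out_dir, "risk_profiles.csv"))
  }

  md <- c("# Descriptive report", "",
          sprintf("%d units, %d clusters, weighted total %.1f", nrow(table),
                  nlevels(factor(.tab_cluster(table))), sum(.tab_weight(table))),
          "", "## Outcome frequencies", "",
          utils::capture.output(print(freq, row.names = FALSE)),
          "", "## Joint 2x2 outcome table", "",
          utils::capture.output(print(jt)))
  writeLines(md, file.path(out_dir, "report.md"))
  files$report <- file.path(out_dir, "report.md")
  .write_meta(out_dir)
  invisible(files)
}

#' Fit the model and write its results
#'
#' @param table a `bivml_table`.
#' @param out_dir output directory.
#' @param covariates1,covariates2 covariate names for the two predictors.
#' @param ... passed to [fit_bivml()].
#' @return the `bivml_fit`, invisibly.
#' @export
run_fit <- function(table, out_dir, covariates1 = character(),
                    covariates2 = character(), ...) {
  .ensure_dir(out_dir)
  fit <- fit_bivml(table, covariates1, covariates2, ...)
  .write_csv(fit$aor_table, file.path(out_dir, "aor_table.csv"))
  jsonlite::write_json(fit_to_list(fit), file.path(out_dir, "fit.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(c(sprintf("logLik %.6f AIC %.4f BIC %.4f", fit$loglik,
                       fit$aic, fit$bic),
               sprintf("convergence: %s after %d evaluations, |grad| %.2e",
                       fit$convergence$status, fit$convergence$iterations,
                       fit$convergence$gradient_norm)),
             file.path(out_dir, "fit.log"))
  .write_meta(out_dir)
  invisible(fit)
}

#' Serialisable summary of a fit
#'
#' @param fit a `bivml_fit`.
#' @return plain list mirroring the fit (JSON-ready).
#' @export
fit_to_list <- function(fit) {
  list(re_structure = fit$params_hat$re_structure,
       theta = as.list(fit$theta), se = as.list(fit$se),
       alpha = fit$association_or$alpha,
       association_or = fit$association_or[c("or", "ci_low", "ci_high", "p")],
       sigma2 = fit$sigma2, icc = fit$icc,
       loglik = fit$loglik, aic = fit$aic, bic = fit$bic,
       n_units = fit$n_units, n_clusters = fit$n_clusters,
       convergence = fit$convergence)
}

#' Fit and write the four-model comparison ladder
#'
#' @param table a `bivml_table`.
#' @param out_dir output directory.
#' @param individual_covs,community_covs covariate names at each level.
#' @param ... passed to [fit_bivml()].
#' @return the `bivml_ladder`, invisibly.
#' @export
run_ladder <- function(table, out_dir, individual_covs, community_covs,
                       ...) {
  .ensure_dir(out_dir)
  lad <- model_ladder(table, individual_covs, community_covs, ...)
  tab <- lad$table
  tab$best_aic <- tab$model == lad$best_aic
  tab$best_bic <- tab$model == lad$best_bic
  .write_csv(tab, file.path(out_dir, "ladder.csv"))
  jsonlite::write_json(list(table = tab, best_aic = lad$best_aic,
                            best_bic = lad$best_bic),
                       file.path(out_dir, "ladder.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  .write_meta(out_dir)
  invisible(lad)
}

#' Simulate a dataset and write it with its configuration
#'
#' @param cfg a `bivml_config`.
#' @param out_dir output directory.
#' @param seed integer seed (echoed in `meta.json`).
#' @return the simulated `bivml_table`, invisibly.
#' @export
run_simulate <- function(cfg, out_dir, seed = cfg$seed) {
  .ensure_dir(out_dir)
  tab <- simulate_bivml(cfg, seed = seed)
  .write_csv(as.data.frame(tab), file.path(out_dir, "dataset.csv"))
  write_config(cfg, file.path(out_dir, "config.yaml"))
  .write_meta(out_dir, seed = seed,
              extra = list(n_units = nrow(tab),
                           n_clusters = cfg$n_clusters))
  invisible(tab)
}

#' Run and write a parameter-recovery experiment
#'
#' @param cfg a `bivml_config`.
#' @param out_dir output directory.
#' @param n_reps number of replicates.
#' @param seeds explicit per-replicate seeds.
#' @param ... passed to [recovery_experiment()].
#' @return the `bivml_recovery`, invisibly.
#' @export
run_recover <- function(cfg, out_dir, n_reps = 20,
                        seeds = seq_len(n_reps), ...) {
  .ensure_dir(out_dir)
  rec <- recovery_experiment(cfg, n_reps = n_reps, seeds = seeds, ...)
  .write_csv(rec$summary, file.path(out_dir, "recovery.csv"))
  jsonlite::write_json(list(summary = rec$summary, n_failed = rec$n_failed,
                            seeds = seeds),
                       file.path(out_dir, "recovery.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  .write_meta(out_dir, seed = seeds[1],
              extra = list(seeds = seeds))
  invisible(rec)
}
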