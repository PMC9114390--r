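#' Minimum sample size under the events-per-variable rule
#'
#' The recruitment floor `n_explanatory * events_per_variable`: with 17
#' explanatory variables and the conventional 10 events per variable, 170.
#'
#' @param n_explanatory number of explanatory variables (positive integer).
#' @param events_per_variable events required per variable (default 10).
#' @return the minimum sample size.
#' @export
#' @examples
#' sample_size_floor(17) # 170
sample_size_floor <- function(n_explanatory, events_per_variable = 10L) {
  if (any(c(n_explanatory, events_per_variable) <= 0) ||
      any(c(n_explanatory, events_per_variable) != round(c(n_explanatory, events_per_variable))))
    stop("inputs must be positive integers")
  as.integer(n_explanatory) * as.integer(events_per_variable)
}

#' Configure a full synthetic study
#'
#' @param configs list of per-country [population_config()]s.
#' @param seed master seed; every stage seed is derived from it with
#'   [derive_seed()].
#' @param nodes quadrature nodes for the mixed logit.
#' @param folds CV folds for the lasso.
#' @param lambda_rule lasso penalty rule (`"min"` or `"1se"`).
#' @param bic_likelihood likelihood entering per-subject BIC
#'   (see [bic_firth()]).
#' @param design_args extra arguments for [generate_design()].
#' @return object of class `study_config`.
#' @export
study_config <- function(configs = list(population_config("KR-like"),
                                        population_config("UK-like")),
                         seed = 1L, nodes = 8L, folds = 10L,
                         lambda_rule = "min",
                         bic_likelihood = "unpenalized",
                         design_args = list()) {
  structure(list(configs = configs, seed = seed, nodes = nodes, folds = folds,
                 lambda_rule = lambda_rule, bic_likelihood = bic_likelihood,
                 design_args = design_args),
            class = "study_config")
}

mixed_logit_formula <- stats::as.formula(
  "choice ~ reward + guilt + inequity_abs + gender + gender:guilt")

group_stage <- function(fits, participants, cfg, what) {
  tab <- build_group_table(fits, participants,
                           with_interactions = (what == "spec2"))
  n <- nrow(tab)
  lasso <- if (n > cfg$folds) {
    cv_lasso(tab, folds = cfg$folds,
             seed = derive_seed(cfg$seed, paste0("folds:", what)),
             lambda_rule = cfg$lambda_rule)
  } else {
    structure(list(flag = "insufficient n", n = n), class = "stage_flag")
  }
  ols <- tryCatch(fit_ols(tab),
                  error = function(e) structure(list(flag = conditionMessage(e)),
                                                class = "stage_flag"))
  list(table = tab, lasso = lasso, ols = ols)
}

#' Run the full study pipeline at desk scale
#'
#' Stages, in order: trial-design generation; per-country cohort sampling
#' and choice simulation; per-participant bias-reduced logistic fits with
#' BIC comparison of the two inequity specifications; per-country
#' random-intercept mixed logit with the Gender x Guilt interaction; the two
#' lasso specifications (9 predictors; 17 with gender interactions) plus the
#' OLS cross-check. Degenerate cohorts do not crash the pipeline: group
#' stages that cannot run are flagged (`"insufficient n"`, rank deficiency
#' messages) in the report.
#'
#' @param cfg a [study_config()].
#' @param dir optional output directory for the artifact bundle (CSV/JSON).
#' @return object of class `study_report`: per-country list with
#'   `prop_abs`, `n`, `mixed` ([fit_mixed_logit()] or a flag), `spec1` /
#'   `spec2` (group tables, lasso and OLS fits or flags), plus `bundle` and
#'   `manifest`.
#' @export
#' @examples
#' \donttest{
#' rep <- run_full_study(study_config(
#'   configs = list(population_config("KR-like", n = 40)), seed = 1))
#' print(rep)
#' }
run_full_study <- function(cfg = study_config(), dir = NULL) {
  stopifnot(inherits(cfg, "study_config"))
  design <- do.call(generate_design,
                    c(list(seed = derive_seed(cfg$seed, "design")), cfg$design_args))
  bundle <- generate_study(cfg$configs, seed = cfg$seed, design = design, dir = dir)
  countries <- unique(bundle$participants$country)
  per_country <- list()
  for (co in countries) {
    parts <- bundle$participants[bundle$participants$country == co, ]
    ch <- bundle$choices[bundle$choices$pid %in% parts$pid, ]
    fits <- batch_fit(ch, design, parts, bic_likelihood = cfg$bic_likelihood)
    long <- merge(join_choices(ch, design), parts[c("pid", "gender")], by = "pid")
    mixed <- tryCatch(
      fit_mixed_logit(mixed_logit_formula, long, group = long$pid,
                      nodes = cfg$nodes),
      error = function(e) structure(list(flag = conditionMessage(e)),
                                    class = "stage_flag"))
    per_country[[co]] <- list(
      n = nrow(parts),
      prop_abs = fits$prop_abs,
      fits = fits,
      mixed = mixed,
      spec1 = group_stage(fits, parts, cfg, "spec1"),
      spec2 = group_stage(fits, parts, cfg, "spec2")
    )
  }
  report <- structure(list(countries = per_country, bundle = bundle,
                           config = cfg, manifest = bundle$manifest),
                      class = "study_report")
  if (!is.null(dir)) write_report_artifacts(report, dir)
  report
}

report_numbers <- function(report) {
  # every printed number, as plain lists (used for report.json and print)
  out <- list()
  for (co in names(report$countries)) {
    r <- report$countries[[co]]
    entry <- list(n = r$n, prop_abs_selected = r$prop_abs)
    if (!inherits(r$mixed, "stage_flag")) {
      entry$mixed <- list(coefficients = as.list(r$mixed$coefficients),
                          se = as.list(r$mixed$se),
                          p_value = as.list(r$mixed$p_value),
                          sigma = r$mixed$sigma, loglik = r$mixed$loglik,
                          mcfadden_r2 = r$mixed$mcfadden_r2,
                          nodes = r$mixed$nodes, scale = "raw")
    } else entry$mixed <- list(flag = r$mixed$flag)
    for (sp in c("spec1", "spec2")) {
      s <- r[[sp]]
      entry[[sp]] <- list(
        lasso = if (inherits(s$lasso, "stage_flag")) list(flag = s$lasso$flag)
        else list(coefficients = as.list(s$lasso$coefficients),
                  chosen_lambda = s$lasso$chosen_lambda,
                  lambda_rule = s$lasso$lambda_choice, scale = "raw"),
        ols = if (inherits(s$ols, "stage_flag")) list(flag = s$ols$flag)
        else list(coefficients = as.list(s$ols$coefficients[, 1]),
                  p_value = as.list(s$ols$coefficients[, 4]), scale = "raw")
      )
    }
    out[[co]] <- entry
  }
  out
}

write_report_artifacts <- function(report, dir) {
  for (co in names(report$countries)) {
    r <- report$countries[[co]]
    slug <- gsub("[^A-Za-z0-9]", "_", co)
    utils::write.csv(r$fits$fits, file.path(dir, paste0("subject_fits_", slug, ".csv")),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(r$fits$selection, file.path(dir, paste0("model_selection_", slug, ".csv")),
                     row.names = FALSE, quote = FALSE)
    for (sp in c("spec1", "spec2"))
      utils::write.csv(as.data.frame(r[[sp]]$table),
                       file.path(dir, paste0("group_table_", sp, "_", slug, ".csv")),
                       row.names = FALSE, quote = FALSE)
  }
  jsonlite::write_json(report_numbers(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.study_report <- function(x, digits = 2, ...) {
  cat("Synthetic trust-game study (master seed ", x$config$seed, ")\n", sep = "")
  for (co in names(x$countries)) {
    r <- x$countries[[co]]
    cat("\n== ", co, " (n = ", r$n, ") ==\n", sep = "")
    cat(sprintf("absolute-difference inequity model selected: %.1f%% of participants\n",
                100 * r$prop_abs))
    if (!inherits(r$mixed, "stage_flag")) {
      cat("mixed logit fixed effects (x 10^3, SE in parentheses):\n")
      est <- r$mixed$coefficients * 1e3
      se <- r$mixed$se * 1e3
      stars <- ifelse(r$mixed$p_value < 0.001, "***",
                      ifelse(r$mixed$p_value < 0.05, "*", ""))
      for (nm in names(est))
        cat(sprintf("  %-14s %10.*f%s (%.*f)\n", nm, digits, est[nm],
                    stars[nm], digits, se[nm]))
      cat(sprintf("  random-intercept SD %.3f; McFadden's R2 %.3f\n",
                  r$mixed$sigma, r$mixed$mcfadden_r2))
    } else cat("mixed logit:", r$mixed$flag, "\n")
    for (sp in c("spec1", "spec2")) {
      s <- r[[sp]]
      lab <- if (sp == "spec1") "lasso (9 predictors)" else "lasso (17 predictors)"
      if (inherits(s$lasso, "stage_flag")) {
        cat(lab, ": ", s$lasso$flag, "\n", sep = "")
      } else {
        nz <- s$lasso$coefficients[s$lasso$coefficients != 0] * 1e3
        cat(lab, ", nonzero coefficients x 10^3:\n", sep = "")
        for (nm in names(nz)) cat(sprintf("  %-26s %10.*f\n", nm, digits, nz[nm]))
      }
    }
  }
  invisible(x)
}
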