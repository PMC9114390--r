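#' Join long-format choices to a design's regressors
#'
#' @param choices data frame with columns `pid`, `trial_id`, `choice` (1 =
#'   cooperate, 0 = defect).
#' @param design a trial-design data frame (see [generate_design()]).
#' @return data frame: choices plus the regressor columns of
#'   [compute_regressors()], one row per (pid, trial).
#' @export
join_choices <- function(choices, design) {
  need <- c("pid", "trial_id", "choice")
  if (!all(need %in% names(choices)))
    stop("choices must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(choices[c("pid", "trial_id")]))
    stop("duplicate (pid, trial_id) records")
  missing_tr <- setdiff(choices$trial_id, design$trial_id)
  if (length(missing_tr))
    stop("trial ids absent from design: ", paste(missing_tr, collapse = ", "))
  reg <- cbind(trial_id = design$trial_id, compute_regressors(design))
  merge(choices, reg, by = "trial_id", sort = FALSE)
}

subject_design_matrix <- function(data, model) {
  switch(model,
    abs = cbind(`(Intercept)` = 1, reward = data$reward, guilt = data$guilt,
                inequity = data$inequity_abs),
    fs = cbind(`(Intercept)` = 1, reward = data$reward, guilt = data$guilt,
               inequity_disadv = data$inequity_disadv,
               inequity_adv = data$inequity_adv)
  )
}

#' Fit one participant's stochastic-choice logistic regression
#'
#' Bias-reduced logistic regression of the cooperate/defect choices on the
#' trial regressors:
#' * `model = "abs"` — `choice ~ reward + guilt + inequity_abs` (the
#'   absolute-difference inequity specification; 4 coefficients),
#' * `model = "fs"` — `choice ~ reward + guilt + inequity_disadv +
#'   inequity_adv` (the Fehr-Schmidt specification; 5 coefficients).
#'
#' BIC uses the trial count as `n` and, by default, the unpenalized
#' log-likelihood at the bias-reduced estimate.
#'
#' @param data one participant's rows from [join_choices()] (columns
#'   `choice` plus the regressors).
#' @param model `"abs"` (default) or `"fs"`.
#' @param bic_likelihood passed to [bic_firth()].
#' @param ... passed to [fit_firth_logistic()].
#' @return object of class `subject_fit` (extends `firth_logit`) with
#'   additional fields `pid`, `model`, `bic`.
#' @export
fit_subject <- function(data, model = c("abs", "fs"),
                        bic_likelihood = "unpenalized", ...) {
  model <- match.arg(model)
  if (nrow(data) < 1L) stop("no trials for this participant")
  x <- subject_design_matrix(data, model)
  fit <- fit_firth_logistic(x, data$choice, ...)
  fit$pid <- if ("pid" %in% names(data)) data$pid[1] else NA
  fit$model <- model
  fit$bic <- bic_firth(fit, bic_likelihood)
  class(fit) <- c("subject_fit", class(fit))
  fit
}

#' Compare the two inequity specifications for one participant
#'
#' Fits both the absolute-difference and the Fehr-Schmidt specification and
#' selects the one with the smaller BIC. A tie selects the
#' absolute-difference model (one fewer parameter).
#'
#' @inheritParams fit_subject
#' @return one-row data frame: `pid`, `bic_abs`, `bic_fs`, `selected`
#'   (`"abs"` or `"fs"`), `margin` (`|bic_abs - bic_fs|`).
#' @export
compare_inequity_models <- function(data, bic_likelihood = "unpenalized", ...) {
  pid <- if ("pid" %in% names(data)) data$pid[1] else NA
  fits <- lapply(c("abs", "fs"), function(m) {
    tryCatch(fit_subject(data, m, bic_likelihood, ...),
             error = function(e) stop("fit failed for pid ", pid, " (", m,
                                      " model): ", conditionMessage(e)))
  })
  bic <- vapply(fits, `[[`, numeric(1), "bic")
  data.frame(pid = pid, bic_abs = bic[1], bic_fs = bic[2],
             selected = if (bic[1] <= bic[2]) "abs" else "fs",
             margin = abs(bic[1] - bic[2]))
}

subject_fit_row <- function(fit) {
  co <- fit$coefficients
  se <- fit$se
  row <- data.frame(pid = fit$pid, model = fit$model,
                    beta0 = co[["(Intercept)"]],
                    beta_reward = co[["reward"]], beta_guilt = co[["guilt"]])
  if (fit$model == "abs") {
    row$beta_inequity <- co[["inequity"]]
    row$beta_ineq_disadv <- NA_real_; row$beta_ineq_adv <- NA_real_
    row$se_inequity <- se[["inequity"]]
    row$se_ineq_disadv <- NA_real_; row$se_ineq_adv <- NA_real_
  } else {
    row$beta_inequity <- NA_real_
    row$beta_ineq_disadv <- co[["inequity_disadv"]]
    row$beta_ineq_adv <- co[["inequity_adv"]]
    row$se_inequity <- NA_real_
    row$se_ineq_disadv <- se[["inequity_disadv"]]
    row$se_ineq_adv <- se[["inequity_adv"]]
  }
  row$se0 <- se[["(Intercept)"]]
  row$se_reward <- se[["reward"]]; row$se_guilt <- se[["guilt"]]
  row$loglik <- fit$loglik; row$bic <- fit$bic; row$converged <- fit$converged
  row
}

#' Fit every participant and tabulate model selection
#'
#' Runs [fit_subject()] under both inequity specifications for each
#' participant and [compare_inequity_models()] across them.
#'
#' @param choices long-format choice data (`pid`, `trial_id`, `choice`).
#' @param design the trial design the choices were collected under.
#' @param participants optional participant table with `pid` (and `country`
#'   for stratified selection proportions).
#' @inheritParams fit_subject
#' @return object of class `batch_fit`: list with `fits` (one row per
#'   (pid, model)), `selection` (one row per pid), `prop_abs` (overall
#'   proportion of participants whose smallest-BIC model is the
#'   absolute-difference one) and `prop_abs_by_country` when country
#'   information is available.
#' @export
batch_fit <- function(choices, design, participants = NULL,
                      bic_likelihood = "unpenalized", ...) {
  long <- join_choices(choices, design)
  pids <- unique(choices$pid)
  if (!length(pids)) stop("no participants in choice data")
  per <- split(long, factor(long$pid, levels = pids))
  fits <- list(); sel <- list()
  for (i in seq_along(per)) {
    d <- per[[i]]
    f_abs <- fit_subject(d, "abs", bic_likelihood, ...)
    f_fs <- fit_subject(d, "fs", bic_likelihood, ...)
    fits[[2 * i - 1]] <- subject_fit_row(f_abs)
    fits[[2 * i]] <- subject_fit_row(f_fs)
    sel[[i]] <- data.frame(pid = d$pid[1], bic_abs = f_abs$bic,
                           bic_fs = f_fs$bic,
                           selected = if (f_abs$bic <= f_fs$bic) "abs" else "fs",
                           margin = abs(f_abs$bic - f_fs$bic))
  }
  fits <- do.call(rbind, fits)
  sel <- do.call(rbind, sel)
  rownames(fits) <- rownames(sel) <- NULL
  out <- list(fits = fits, selection = sel,
              prop_abs = mean(sel$selected == "abs"))
  if (!is.null(participants) && "country" %in% names(participants)) {
    sel2 <- merge(sel, participants[c("pid", "country")], by = "pid")
    out$prop_abs_by_country <- tapply(sel2$selected == "abs", sel2$country, mean)
  }
  class(out) <- "batch_fit"
  out
}

#' @export
print.batch_fit <- function(x, ...) {
  n <- nrow(x$selection)
  cat("Per-participant fits:", n, "participants x 2 inequity models\n")
  cat(sprintf("absolute-difference model selected for %d/%d (%.1f%%)\n",
              sum(x$selection$selected == "abs"), n, 100 * x$prop_abs))
  if (!is.null(x$prop_abs_by_country)) {
    cat("by country:\n")
    print(round(100 * x$prop_abs_by_country, 1))
  }
  invisible(x)
}
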