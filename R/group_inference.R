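group_predictors <- c("gender", "neuroticism", "extraversion", "openness",
                      "agreeableness", "conscientiousness", "age",
                      "education", "income")

#' Build the participant-level table for group regressions
#'
#' One row per participant: the target `beta_guilt` (the guilt coefficient
#' from that participant's absolute-difference subject fit) and the
#' predictors gender (men = 1), the five Big Five scores, age, education and
#' income — 9 predictors; with `with_interactions = TRUE`, additionally the
#' 8 gender x covariate product columns, for 17.
#'
#' @param fits a [batch_fit()] result (or its `fits` data frame).
#' @param participants participant covariate table.
#' @param with_interactions add the `gender_x_*` product columns.
#' @param center_interactions multiply gender by the centered (rather than
#'   raw) covariate when forming interactions.
#' @return object of class `group_table`: data frame with `pid`,
#'   `beta_guilt` and the predictor columns; constant (zero-variance)
#'   predictor columns are flagged for removal in attribute
#'   `"constant_columns"`.
#' @export
build_group_table <- function(fits, participants, with_interactions = FALSE,
                              center_interactions = FALSE) {
  ftab <- if (inherits(fits, "batch_fit")) fits$fits else fits
  ftab <- ftab[ftab$model == "abs", c("pid", "beta_guilt")]
  missing_cov <- setdiff(group_predictors, names(participants))
  if (length(missing_cov))
    stop("participant table lacks covariates: ", paste(missing_cov, collapse = ", "))
  unmatched <- setdiff(ftab$pid, participants$pid)
  if (length(unmatched))
    stop("no participant row for pid: ", paste(unmatched, collapse = ", "))
  tab <- merge(ftab, participants[c("pid", group_predictors)], by = "pid")
  if (with_interactions) {
    for (v in setdiff(group_predictors, "gender")) {
      cov <- if (center_interactions) tab[[v]] - mean(tab[[v]]) else tab[[v]]
      tab[[paste0("gender_x_", v)]] <- tab$gender * cov
    }
  }
  pred <- setdiff(names(tab), c("pid", "beta_guilt"))
  const <- pred[vapply(tab[pred], function(z) stats::var(z) == 0, logical(1))]
  attr(tab, "constant_columns") <- const
  attr(tab, "predictors") <- pred
  class(tab) <- c("group_table", "data.frame")
  tab
}

group_xy <- function(table, drop_constant = TRUE) {
  pred <- attr(table, "predictors")
  if (is.null(pred)) pred <- setdiff(names(table), c("pid", "beta_guilt"))
  const <- attr(table, "constant_columns")
  if (drop_constant && length(const)) pred <- setdiff(pred, const)
  list(x = as.matrix(as.data.frame(table)[pred]), y = table$beta_guilt,
       dropped = const)
}

#' Lasso regression of guilt sensitivity with cross-validated penalty
#'
#' L1-penalized least squares of `beta_guilt` on the group-table predictors,
#' with the penalty weight chosen by ten-fold cross-validation (seeded fold
#' assignment). Solved by glmnet's coordinate descent on the objective
#' `(1/2n) * RSS + lambda * sum |beta_j|`; predictors are standardized
#' internally and coefficients reported on the original scale; the intercept
#' is unpenalized.
#'
#' @param table a [build_group_table()] result (constant columns are dropped
#'   with a message).
#' @param folds number of CV folds (default 10); requires `n > folds`.
#' @param seed integer seed for the fold assignment.
#' @param lambda_rule `"min"` (lambda at minimum CV error, default) or
#'   `"1se"` (largest lambda within one standard error of the minimum).
#' @param lambda optional user lambda grid (decreasing).
#' @return object of class `lasso_fit`: `lambda` (grid), `path`
#'   (coefficient path, rows = predictors), `cvm`/`cvsd` (CV error curve),
#'   `lambda_choice`, `chosen_lambda`, `coefficients` (at the chosen lambda,
#'   incl. intercept, original scale, scale field `"raw"`), `foldid`,
#'   `dropped`.
#' @export
cv_lasso <- function(table, folds = 10L, seed = 1L,
                     lambda_rule = c("min", "1se"), lambda = NULL) {
  lambda_rule <- match.arg(lambda_rule)
  xy <- group_xy(table)
  n <- length(xy$y)
  if (n <= folds) stop("need more observations (", n, ") than folds (", folds, ")")
  if (stats::var(xy$y) == 0) stop("target beta_guilt is constant")
  if (length(xy$dropped))
    message("dropping constant predictor columns: ",
            paste(xy$dropped, collapse = ", "))
  foldid <- with_seed(seed, sample(rep(seq_len(folds), length.out = n)))
  cv <- glmnet::cv.glmnet(xy$x, xy$y, alpha = 1, foldid = foldid,
                          lambda = lambda, standardize = TRUE, thresh = 1e-12,
                          maxit = 1e7)
  chosen <- if (lambda_rule == "min") cv$lambda.min else cv$lambda.1se
  co <- as.matrix(stats::coef(cv, s = chosen))
  path <- as.matrix(cv$glmnet.fit$beta)
  structure(list(
    lambda = cv$lambda, path = path, cvm = cv$cvm, cvsd = cv$cvsd,
    lambda_choice = lambda_rule, chosen_lambda = chosen,
    coefficients = stats::setNames(drop(co), rownames(co)),
    scale = "raw", foldid = foldid, dropped = xy$dropped,
    n = n, cv = cv
  ), class = "lasso_fit")
}

#' @export
coef.lasso_fit <- function(object, ...) object$coefficients

#' @export
print.lasso_fit <- function(x, ...) {
  cat("Lasso regression of beta(Guilt), 10-fold CV (n = ", x$n,
      ", lambda.", x$lambda_choice, " = ", format(x$chosen_lambda, digits = 4),
      ")\n", sep = "")
  nz <- x$coefficients[x$coefficients != 0]
  print(round(nz, 4))
  zero <- setdiff(names(x$coefficients), names(nz))
  if (length(zero)) cat("zeroed:", paste(zero, collapse = ", "), "\n")
  invisible(x)
}

#' Lasso coefficients at exact penalty values
#'
#' Thin solver used for closed-form and KKT verification: coefficients of
#' the objective `(1/2n) * RSS + lambda * sum w_j |beta_j|` at the requested
#' `lambda` exactly (glmnet refit at that value).
#'
#' @param x predictor matrix (at least two columns; a single-predictor
#'   problem can be augmented with a column exactly orthogonal to the others
#'   and to `y`, which provably leaves the solution unchanged).
#' @param y response.
#' @param lambda penalty value(s).
#' @param standardize standardize predictors internally (glmnet's 1/n SD).
#' @return coefficient matrix (rows: intercept then predictors; one column
#'   per lambda).
#' @export
lasso_at <- function(x, y, lambda, standardize = TRUE) {
  fit <- glmnet::glmnet(x, y, alpha = 1, standardize = standardize,
                        thresh = 1e-14)
  as.matrix(stats::coef(fit, s = lambda, exact = TRUE, x = x, y = y,
                        alpha = 1, standardize = standardize, thresh = 1e-14))
}

#' KKT residuals of a lasso solution
#'
#' For the objective `(1/2n) * ||y - b0 - X b||^2 + lambda * sum s_j |b_j|`
#' (with `s_j` the glmnet 1/n standard deviation of column `j` when the fit
#' was standardized, else 1), stationarity requires
#' `(1/n) x_j' r = lambda * s_j * sign(b_j)` for active coefficients and
#' `|(1/n) x_j' r| <= lambda * s_j` for zeroed ones. Returns the amount by
#' which each condition is violated (0 = satisfied).
#'
#' @param x,y data the solution was computed from.
#' @param coefficients named vector, intercept first (as from [lasso_at()] or
#'   a [cv_lasso()] fit).
#' @param lambda the penalty the solution corresponds to.
#' @param standardize whether the fit standardized predictors.
#' @return numeric vector of per-coefficient violations.
#' @export
lasso_kkt <- function(x, y, coefficients, lambda, standardize = TRUE) {
  b0 <- coefficients[1]
  b <- coefficients[-1]
  n <- nrow(x)
  s <- if (standardize) sqrt(colMeans(scale(x, scale = FALSE)^2)) else rep(1, ncol(x))
  r <- y - b0 - drop(x %*% b)
  g <- drop(crossprod(x, r)) / n
  ifelse(b != 0,
         abs(g - lambda * s * sign(b)),
         pmax(abs(g) - lambda * s, 0))
}

#' Ordinary-least-squares cross-check of the group regression
#'
#' The same design as [cv_lasso()] fitted by unpenalized least squares with
#' two-sided t-tests. Under strong collinearity (e.g. the 17-column
#' interaction specification) the design can be rank deficient; this is
#' reported as an error naming the aliased columns rather than silently
#' dropping them.
#'
#' @param table a [build_group_table()] result.
#' @return object of class `ols_fit`: `coefficients` matrix (estimate, SE,
#'   t, p), `sigma`, `r_squared`, `df_residual`, and the underlying `lm`.
#' @export
fit_ols <- function(table) {
  xy <- group_xy(table, drop_constant = FALSE)
  n <- length(xy$y)
  if (n <= ncol(xy$x) + 1)
    stop("need more observations (", n, ") than coefficients (", ncol(xy$x) + 1, ")")
  X <- cbind(`(Intercept)` = 1, xy$x)
  q <- qr(X)
  if (q$rank < ncol(X)) {
    aliased <- colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear columns: ",
         paste(aliased, collapse = ", "))
  }
  df <- data.frame(beta_guilt = xy$y, xy$x, check.names = FALSE)
  fit <- stats::lm(beta_guilt ~ ., data = df)
  sm <- summary(fit)
  structure(list(coefficients = sm$coefficients, sigma = sm$sigma,
                 r_squared = sm$r.squared, df_residual = fit$df.residual,
                 lm = fit), class = "ols_fit")
}

#' @export
coef.ols_fit <- function(object, ...) object$coefficients[, 1]

#' @export
print.ols_fit <- function(x, ...) {
  cat("OLS cross-check of the group regression (df =", x$df_residual, ")\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat("residual SD:", format(x$sigma, digits = 4),
      " R2:", format(x$r_squared, digits = 3), "\n")
  invisible(x)
}
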