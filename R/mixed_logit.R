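#' Gauss-Hermite nodes and weights
#'
#' Golub-Welsch computation from the symmetric tridiagonal Jacobi matrix of
#' the Hermite polynomials (weight `exp(-x^2)` on the real line).
#'
#' @param n number of quadrature nodes.
#' @return list with `nodes` and `weights` (weights sum to `sqrt(pi)`).
#' @keywords internal
gauss_hermite <- function(n) {
  stopifnot(n >= 1)
  if (n == 1) return(list(nodes = 0, weights = sqrt(pi)))
  off <- sqrt(seq_len(n - 1) / 2)
  J <- matrix(0, n, n)
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- off
  J[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  idx <- order(e$values)
  list(nodes = e$values[idx], weights = sqrt(pi) * e$vectors[1, idx]^2)
}

logsumexp_rows <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

# marginal log-likelihood (and gradient) of a random-intercept logit model
# via non-adaptive Gauss-Hermite quadrature.
# X: n_obs x p fixed-effect design; y: 0/1; gi: integer group index 1..G.
mixed_logit_objective <- function(theta, X, y, gi, gh, grad = FALSE) {
  p <- ncol(X)
  beta <- theta[seq_len(p)]
  sigma <- theta[p + 1L]
  K <- length(gh$nodes)
  G <- max(gi)
  eta0 <- drop(X %*% beta)
  offs <- sqrt(2) * sigma * gh$nodes # per-node random-intercept values
  sgn <- 2 * y - 1
  # log Bernoulli likelihood per observation and node: log plogis(sgn * eta)
  ETA <- outer(eta0, offs, `+`)
  LL <- stats::plogis(sgn * ETA, log.p = TRUE)
  logA <- rowsum(LL, gi) # G x K: per-group conditional log-likelihoods
  lw <- log(gh$weights) - 0.5 * log(pi)
  M <- sweep(logA, 2, lw, `+`)
  li <- logsumexp_rows(M) # per-group marginal log-likelihood
  ll <- sum(li)
  if (!grad) return(ll)
  C <- exp(M - li) # G x K posterior node weights, rows sum to 1
  R <- (y - stats::plogis(ETA)) # n_obs x K residuals
  Cw <- C[gi, , drop = FALSE]
  g_beta <- drop(crossprod(X, rowSums(R * Cw)))
  S <- rowsum(R, gi) # G x K summed residuals
  g_sigma <- sqrt(2) * sum((C * S) %*% gh$nodes)
  list(ll = ll, gradient = c(g_beta, g_sigma), li = li)
}

#' Marginal log-likelihood of a random-intercept logistic model
#'
#' Evaluates, at fixed parameter values, the Gauss-Hermite approximation to
#' the marginal log-likelihood in which each group's intercept deviation is
#' `N(0, sigma^2)` and integrated out. Exposed so the quadrature can be
#' checked against brute-force integration.
#'
#' @param beta fixed-effect coefficient vector (matching `x`'s columns).
#' @param sigma random-intercept standard deviation (>= 0).
#' @param x fixed-effects design matrix.
#' @param y binary response.
#' @param group grouping vector (one level per participant).
#' @param nodes number of quadrature nodes.
#' @return the marginal log-likelihood (sum over groups).
#' @export
mixed_logit_loglik <- function(beta, sigma, x, y, group, nodes = 8L) {
  gi <- as.integer(factor(group))
  mixed_logit_objective(c(beta, sigma), as.matrix(x), y, gi,
                        gauss_hermite(nodes), grad = FALSE)
}

#' Random-intercept mixed logistic regression
#'
#' Fits a logistic regression with a Gaussian per-group intercept by direct
#' maximization of the Gauss-Hermite marginal likelihood (non-adaptive
#' quadrature, analytic gradient, L-BFGS-B with `sigma >= 0`). The default
#' model for choice data is
#' `choice ~ reward + guilt + inequity_abs + gender + gender:guilt` with the
#' participant as the grouping factor, i.e. the group-level test of whether
#' men's choices respond more strongly to guilt than women's.
#'
#' McFadden's pseudo-R-squared is reported against an intercept-only
#' ordinary logistic null.
#'
#' @param formula model formula for the fixed effects (binary response on
#'   the left).
#' @param data data frame containing the model variables.
#' @param group grouping factor (participant ids), length `nrow(data)`, or
#'   the name of a column of `data`.
#' @param nodes Gauss-Hermite node count (default 8; >= 4).
#' @param start optional start values `c(beta, sigma)`.
#' @param control options for [stats::optim()]'s L-BFGS-B; the default
#'   `factr = 1e5` converges coefficients well past the reporting precision.
#'   Replicate-heavy simulation studies can relax it (e.g. `factr = 1e7`).
#' @return object of class `mixed_logit`: `coefficients`, `se`, `z`,
#'   `p_value`, `sigma` (random-intercept SD), `loglik`, `null_loglik`,
#'   `mcfadden_r2`, `vcov`, `nodes`, `converged`, `n_obs`, `n_groups`.
#' @export
#' @examples
#' \donttest{
#' d <- generate_design(seed = 1)
#' cfg <- population_config("KR-like", n = 60)
#' pop <- sample_participants(cfg, seed = 2)
#' ch <- simulate_choices(pop$participants, pop$truth, d, seed = 3)
#' long <- merge(join_choices(ch, d), pop$participants[c("pid", "gender")])
#' fit_mixed_logit(choice ~ reward + guilt + inequity_abs + gender +
#'                   gender:guilt, long, group = "pid")
#' }
fit_mixed_logit <- function(formula, data, group, nodes = 8L, start = NULL,
                            control = list(maxit = 1000, factr = 1e5)) {
  if (nodes < 4L) stop("at least 4 quadrature nodes are required")
  if (is.character(group) && length(group) == 1L) group <- data[[group]]
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  if (!all(y %in% c(0, 1))) stop("response must be binary 0/1")
  X <- stats::model.matrix(formula, mf)
  if (qr(X)$rank < ncol(X)) stop("fixed-effects design is singular")
  gi <- as.integer(factor(group))
  G <- max(gi)
  if (G < 2L) stop("at least 2 groups are required")
  gh <- gauss_hermite(nodes)
  p <- ncol(X)

  if (is.null(start)) {
    g0 <- stats::glm.fit(X, y, family = stats::binomial())
    start <- c(g0$coefficients, 0.5)
  }
  # optim calls fn and gr back to back at the same point; cache the shared work
  cache <- new.env(parent = emptyenv())
  evaluate <- function(th) {
    key <- paste(th, collapse = ",")
    if (!identical(cache$key, key)) {
      cache$val <- mixed_logit_objective(th, X, y, gi, gh, grad = TRUE)
      cache$key <- key
    }
    cache$val
  }
  fn <- function(th) -evaluate(th)$ll
  gr <- function(th) -evaluate(th)$gradient
  opt <- stats::optim(start, fn, gr, method = "L-BFGS-B",
                      lower = c(rep(-Inf, p), 0), control = control)
  theta <- opt$par
  H <- stats::optimHess(theta, fn, gr)
  vc <- tryCatch(solve(H), error = function(e) {
    # sigma on the boundary can make the full Hessian singular;
    # fall back to the fixed-effects block
    vb <- matrix(NA_real_, p + 1, p + 1)
    vb[seq_len(p), seq_len(p)] <- solve(H[seq_len(p), seq_len(p)])
    vb
  })
  beta <- stats::setNames(theta[seq_len(p)], colnames(X))
  se <- sqrt(pmax(diag(vc)[seq_len(p)], 0))
  z <- beta / se
  ll <- -opt$value
  # intercept-only ordinary logistic null for McFadden's pseudo-R2
  pbar <- mean(y)
  ll0 <- sum(stats::dbinom(y, 1, pbar, log = TRUE))
  structure(list(
    coefficients = beta, se = stats::setNames(se, colnames(X)), z = z,
    p_value = 2 * stats::pnorm(-abs(z)),
    sigma = unname(theta[p + 1L]),
    se_sigma = unname(sqrt(max(vc[p + 1, p + 1], 0))),
    vcov = vc, loglik = ll, null_loglik = ll0,
    mcfadden_r2 = mcfadden_r2(ll, ll0),
    nodes = nodes, converged = opt$convergence == 0,
    n_obs = length(y), n_groups = G, formula = formula
  ), class = "mixed_logit")
}

#' @export
coef.mixed_logit <- function(object, ...) object$coefficients

#' @export
vcov.mixed_logit <- function(object, ...) object$vcov

#' @export
logLik.mixed_logit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients) + 1,
            nobs = object$n_obs, class = "logLik")
}

#' @export
print.mixed_logit <- function(x, ...) {
  cat("Random-intercept mixed logistic regression (",
      x$n_obs, " obs, ", x$n_groups, " groups, ",
      x$nodes, "-node Gauss-Hermite)\n", sep = "")
  print(round(rbind(estimate = x$coefficients, se = x$se), 4))
  cat("random-intercept SD:", format(x$sigma, digits = 4),
      " log-likelihood:", format(x$loglik, digits = 6), "\n")
  cat("McFadden's R2:", format(x$mcfadden_r2, digits = 3), "\n")
  invisible(x)
}

#' @export
summary.mixed_logit <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `z value` = object$z, `Pr(>|z|)` = object$p_value)
  structure(list(coefficients = tab, sigma = object$sigma,
                 loglik = object$loglik, mcfadden_r2 = object$mcfadden_r2,
                 n_obs = object$n_obs, n_groups = object$n_groups),
            class = "summary.mixed_logit")
}

#' @export
print.summary.mixed_logit <- function(x, ...) {
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat("random-intercept SD:", format(x$sigma, digits = 4),
      " McFadden's R2:", format(x$mcfadden_r2, digits = 3), "\n")
  invisible(x)
}

#' McFadden's pseudo-R-squared
#'
#' `1 - ll_model / ll_null` for likelihood-based binary models.
#'
#' @param ll_model maximized model log-likelihood (<= 0).
#' @param ll_null log-likelihood of the null (intercept-only) model (< 0).
#' @return the ratio; 0 when the model adds nothing, approaching 1 for a
#'   perfect model.
#' @export
#' @examples
#' mcfadden_r2(-100, -120) # 0.1667
mcfadden_r2 <- function(ll_model, ll_null) {
  if (ll_null >= 0) stop("null log-likelihood must be negative")
  if (ll_model > 0) stop("model log-likelihood must be <= 0")
  1 - ll_model / ll_null
}
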