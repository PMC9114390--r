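#' Structural preference parameters for Player B
#'
#' Bundles the second mover's sensitivities: `gamma` (guilt, utility cost per
#' point of belief-weighted harm `tau * (x_A - y_A)` incurred by defecting),
#' `alpha` (absolute-difference inequity), `phi` / `omega` (Fehr-Schmidt
#' disadvantageous / advantageous inequity), plus a choice `intercept` (bias
#' on the utility-difference scale) and a `temperature` scaling the utility
#' difference before the logistic (1 = utilities in raw points). Only
#' Player B carries these parameters: guilt sensitivity is role-dependent
#' and the first mover has no move after trust.
#'
#' @param gamma,alpha,phi,omega non-negative sensitivities.
#' @param intercept choice bias on the log-odds scale (default 0).
#' @param temperature positive scale on the utility difference (default 1).
#' @return object of class `agent_params` (named list).
#' @export
#' @examples
#' agent_params(gamma = 0.6, alpha = 0.2)
agent_params <- function(gamma = 0, alpha = 0, phi = 0, omega = 0,
                         intercept = 0, temperature = 1) {
  stopifnot(gamma >= 0, alpha >= 0, phi >= 0, omega >= 0, temperature > 0)
  structure(list(gamma = gamma, alpha = alpha, phi = phi, omega = omega,
                 intercept = intercept, temperature = temperature),
            class = "agent_params")
}

#' @export
print.agent_params <- function(x, ...) {
  cat("Player B preferences: gamma =", x$gamma, " alpha =", x$alpha,
      " phi =", x$phi, " omega =", x$omega,
      "\n  intercept =", x$intercept, " temperature =", x$temperature, "\n")
  invisible(x)
}

check_profile <- function(profile) {
  profile <- match.arg(profile, c("cooperate", "defect", "Z"))
  if (profile == "Z")
    stop("Player B has no move at the outside option Z; utilities are defined only for (W, Cooperate) and (W, Defect)")
  profile
}

#' Player B utilities under the three structural specifications
#'
#' @description
#' For the profile (W, Cooperate) payoffs are `(x_A, x_B)`; for (W, Defect),
#' `(y_A, y_B)`. The three specifications are:
#'
#' * `utility_abs` — absolute-difference inequity aversion:
#'   `x_B - alpha * |x_A - x_B|` when cooperating,
#'   `y_B - alpha * |y_A - y_B|` when defecting.
#' * `utility_fs` — Fehr-Schmidt inequity aversion:
#'   `x_B - phi * max(x_A - x_B, 0) - omega * max(x_B - x_A, 0)` when
#'   cooperating (analogously with the y-payoffs when defecting).
#' * `utility_combined` — belief-dependent guilt plus absolute inequity:
#'   cooperation as in `utility_abs`; defection additionally costs
#'   `gamma * tau * (x_A - y_A)`, the guilt from disappointing A relative to
#'   A's expectation.
#'
#' A narrowly self-interested agent is the special case where all
#' sensitivities are zero: utility equals the monetary payoff.
#'
#' @param trials trial(s): list or data frame with payoff columns and `tau`.
#' @param params an [agent_params()] object.
#' @param profile `"cooperate"` or `"defect"` (the outside option `"Z"` is
#'   rejected: Player B never moves there).
#' @return numeric vector of utilities in points, one per trial.
#' @export
#' @examples
#' tr <- list(x_A = 12, x_B = 10, y_A = 4, y_B = 16, tau = 0.8)
#' utility_abs(tr, agent_params(alpha = 0.3), "cooperate")       # 9.4
#' utility_combined(tr, agent_params(gamma = 0.5, alpha = 0.1), "defect")
utility_abs <- function(trials, params, profile) {
  profile <- check_profile(profile)
  t <- as.data.frame(as.list(trials))
  if (profile == "cooperate") t$x_B - params$alpha * abs(t$x_A - t$x_B)
  else t$y_B - params$alpha * abs(t$y_A - t$y_B)
}

#' @rdname utility_abs
#' @export
utility_fs <- function(trials, params, profile) {
  profile <- check_profile(profile)
  t <- as.data.frame(as.list(trials))
  if (profile == "cooperate")
    t$x_B - params$phi * pmax(t$x_A - t$x_B, 0) - params$omega * pmax(t$x_B - t$x_A, 0)
  else
    t$y_B - params$phi * pmax(t$y_A - t$y_B, 0) - params$omega * pmax(t$y_B - t$y_A, 0)
}

#' @rdname utility_abs
#' @export
utility_combined <- function(trials, params, profile) {
  profile <- check_profile(profile)
  t <- as.data.frame(as.list(trials))
  if (profile == "cooperate") t$x_B - params$alpha * abs(t$x_A - t$x_B)
  else t$y_B - params$gamma * t$tau * (t$x_A - t$y_A) -
    params$alpha * abs(t$y_A - t$y_B)
}

#' Deterministic guilt-averse choice
#'
#' A purely guilt-averse Player B cooperates iff
#' `y_B - gamma * tau * (x_A - y_A) < x_B` (strict). Exact indifference
#' resolves to Defect, matching the strict inequality.
#'
#' @param trials trial(s) as in [utility_abs()].
#' @param gamma non-negative guilt sensitivity.
#' @return character vector, `"cooperate"` or `"defect"` per trial.
#' @export
#' @examples
#' tr <- list(x_A = 12, x_B = 10, y_A = 4, y_B = 16, tau = 0.8)
#' cooperate_deterministic(tr, gamma = 1.0) # cooperate
#' cooperate_deterministic(tr, gamma = 0.9) # defect
cooperate_deterministic <- function(trials, gamma) {
  stopifnot(gamma >= 0)
  t <- as.data.frame(as.list(trials))
  ifelse(t$y_B - gamma * t$tau * (t$x_A - t$y_A) < t$x_B, "cooperate", "defect")
}

#' Stochastic-choice probability of cooperating
#'
#' Logistic choice rule
#' `P(cooperate) = plogis(temperature * (u(cooperate) - u(defect)) + intercept)`
#' under one of the three structural utility specifications. With
#' temperature 1 and intercept 0 this is the inverse-logit of the raw
#' utility difference, and for the combined model the log-odds decompose
#' exactly as `reward + gamma * guilt + alpha * inequity_abs` in the
#' regressors of [compute_regressors()].
#'
#' @param trials trial(s) as in [utility_abs()].
#' @param params an [agent_params()] object.
#' @param model `"combined"` (default), `"abs"` or `"fs"`.
#' @return numeric vector of probabilities, strictly inside (0, 1).
#' @export
#' @examples
#' tr <- list(x_A = 12, x_B = 10, y_A = 4, y_B = 16, tau = 0.8)
#' choice_probability(tr, agent_params(gamma = 1), "combined") # ~0.5987
choice_probability <- function(trials, params, model = c("combined", "abs", "fs")) {
  model <- match.arg(model)
  u <- switch(model,
    combined = utility_combined(trials, params, "cooperate") -
      utility_combined(trials, params, "defect"),
    abs = utility_abs(trials, params, "cooperate") -
      utility_abs(trials, params, "defect"),
    fs = utility_fs(trials, params, "cooperate") -
      utility_fs(trials, params, "defect")
  )
  stats::plogis(params$temperature * u + params$intercept)
}
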