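#' Belief schedules, payoff validation and psychological regressors
#'
#' The task is a binary trust game. Player A either opts out (payoffs
#' `z_A`, `z_B`) or signals trust; after trust, Player B chooses Cooperate
#' (payoffs `x_A`, `x_B`) or Defect (`y_A`, `y_B`). Player A also states a
#' belief `tau` that B will cooperate. A design is a data frame with one row
#' per trial and columns `trial_id, x_A, x_B, y_A, y_B, z_A, z_B, tau`
#' (`tau` a fraction in [0, 1]).
#'
#' Two payoff orderings define the game: `y_A < z_A < x_A` (trust is costly
#' for A, so choosing in signals trust) and `z_B < x_B < y_B` (B is tempted
#' to defect, so defecting disappoints A and can induce guilt).
#'
#' @name task_design
NULL

# default belief schedule: level (fraction) -> number of trials
default_tau_counts <- function() {
  c("0.6" = 7L, "0.7" = 5L, "0.8" = 13L, "0.9" = 11L, "1" = 9L)
}

#' Build a randomized belief (tau) schedule
#'
#' Expands a `level -> count` table into a sequence of per-trial belief
#' probabilities and applies a seeded permutation (trial order was randomized
#' across participants in the task this emulates). Levels given in percent
#' (> 1) are converted to fractions.
#'
#' @param counts_by_level named numeric vector: names are tau levels (fraction
#'   in `[0, 1]`, or percent in `(1, 100]`), values are positive integer trial
#'   counts. Default: 60% x7, 70% x5, 80% x13, 90% x11, 100% x9 (45 trials).
#' @param seed integer seed for the permutation, or `NULL` to keep the
#'   expansion order.
#' @return numeric vector of tau fractions, one per trial.
#' @export
#' @examples
#' tau <- build_tau_schedule(seed = 1)
#' length(tau)     # 45
#' table(tau)
build_tau_schedule <- function(counts_by_level = default_tau_counts(), seed = NULL) {
  if (is.null(names(counts_by_level)) || anyNA(suppressWarnings(as.numeric(names(counts_by_level)))))
    stop("counts_by_level must be a named vector with numeric tau levels as names")
  levels <- as.numeric(names(counts_by_level))
  counts <- as.vector(counts_by_level)
  if (any(counts <= 0) || any(counts != round(counts)))
    stop("trial counts must be positive integers")
  # accept percent input explicitly: anything > 1 is treated as percent
  pct <- levels > 1
  levels[pct] <- levels[pct] / 100
  if (any(levels < 0 | levels > 1))
    stop("tau levels must lie in [0, 1] after percent conversion")
  tau <- rep(levels, times = counts)
  if (!is.null(seed)) tau <- with_seed(seed, sample(tau))
  tau
}

#' Validate a trial's payoff orderings
#'
#' Checks the two strict chains that define the game: `y_A < z_A < x_A`
#' (Player A's trust condition) and `z_B < x_B < y_B` (Player B's
#' temptation/guilt condition). Total function: never throws, always returns
#' a verdict.
#'
#' @param payoffs a list or one-row data frame with fields
#'   `x_A, x_B, y_A, y_B, z_A, z_B`.
#' @return a list with `valid` (logical) and `violations` (character vector
#'   naming each failed strict inequality, empty when valid).
#' @export
#' @examples
#' validate_payoffs(list(x_A = 12, x_B = 10, y_A = 4, y_B = 16, z_A = 8, z_B = 6))
validate_payoffs <- function(payoffs) {
  p <- as.list(payoffs)
  need <- c("x_A", "x_B", "y_A", "y_B", "z_A", "z_B")
  if (!all(need %in% names(p))) stop("payoffs must contain ", paste(need, collapse = ", "))
  checks <- c(
    "y_A < z_A" = p$y_A < p$z_A,
    "z_A < x_A" = p$z_A < p$x_A,
    "z_B < x_B" = p$z_B < p$x_B,
    "x_B < y_B" = p$x_B < p$y_B
  )
  violations <- if (all(checks)) character(0) else
    paste(names(checks)[!checks], "violated")
  list(valid = all(checks), violations = violations)
}

#' Compute the per-trial psychological regressors
#'
#' For each trial, the three regressors of the stochastic-choice logistic
#' model, plus the two Fehr-Schmidt inequity components used by the
#' alternative inequity specification. All are differences between the
#' Cooperate and Defect allocations:
#' \describe{
#'   \item{reward}{`x_B - y_B`, B's monetary gain from cooperating (negative
#'     by design, since `x_B < y_B`).}
#'   \item{guilt}{`tau * (x_A - y_A)`, the belief-weighted harm to A that
#'     defecting would inflict relative to what A expects.}
#'   \item{inequity_abs}{`-(|x_A - x_B| - |y_A - y_B|)`, the reduction in
#'     absolute payoff inequality achieved by cooperating.}
#'   \item{inequity_disadv}{`-(max(x_A - x_B, 0) - max(y_A - y_B, 0))`,
#'     the disadvantageous-inequality component.}
#'   \item{inequity_adv}{`-(max(x_B - x_A, 0) - max(y_B - y_A, 0))`,
#'     the advantageous-inequality component.}
#' }
#'
#' @param trials a design data frame (or single trial as list/one-row data
#'   frame) with payoff columns and `tau` as a fraction.
#' @return data frame with columns `reward`, `guilt`, `inequity_abs`,
#'   `inequity_disadv`, `inequity_adv`, one row per trial.
#' @export
#' @examples
#' compute_regressors(list(x_A = 12, x_B = 10, y_A = 4, y_B = 16, tau = 0.8))
compute_regressors <- function(trials) {
  t <- as.data.frame(as.list(trials))[c("x_A", "x_B", "y_A", "y_B", "tau")]
  data.frame(
    reward = t$x_B - t$y_B,
    guilt = t$tau * (t$x_A - t$y_A),
    inequity_abs = -(abs(t$x_A - t$x_B) - abs(t$y_A - t$y_B)),
    inequity_disadv = -(pmax(t$x_A - t$x_B, 0) - pmax(t$y_A - t$y_B, 0)),
    inequity_adv = -(pmax(t$x_B - t$x_A, 0) - pmax(t$y_B - t$y_A, 0))
  )
}

#' Correlation diagnostics for a trial design
#'
#' Pairwise Pearson correlations among the `reward`, `guilt` and
#' `inequity_abs` regressors, with flags against configured bounds. Fewer
#' than 3 trials, or a zero-variance regressor, yields an `insufficient`
#' flag / `NA` correlations rather than an error.
#'
#' @param design a trial-design data frame.
#' @param max_abs_r bound on every pairwise `|r|` (default 0.30).
#' @param max_abs_r_guilt_inequity tighter bound on `|r(guilt, inequity_abs)|`
#'   (default 0.05); the design treats guilt and inequity as the pair that
#'   must be orthogonal.
#' @return object of class `design_diagnostics`: list with `cor` (3x3
#'   symmetric matrix), `max_abs_r`, `r_guilt_inequity`, `within_bounds`
#'   (logical or `NA`), and `flags` (character).
#' @export
design_diagnostics <- function(design, max_abs_r = 0.30,
                               max_abs_r_guilt_inequity = 0.05) {
  reg <- compute_regressors(design)[c("reward", "guilt", "inequity_abs")]
  flags <- character()
  if (nrow(reg) < 3L) {
    flags <- "insufficient trials"
    cm <- matrix(NA_real_, 3, 3, dimnames = list(names(reg), names(reg)))
    diag(cm) <- 1
  } else {
    sds <- vapply(reg, stats::sd, numeric(1))
    if (any(sds == 0))
      flags <- paste0("zero variance: ", paste(names(reg)[sds == 0], collapse = ", "))
    cm <- suppressWarnings(stats::cor(reg))
    diag(cm) <- 1
  }
  off <- cm[upper.tri(cm)]
  max_off <- if (all(is.na(off))) NA_real_ else max(abs(off), na.rm = TRUE)
  rgi <- cm["guilt", "inequity_abs"]
  within <- if (is.na(max_off) || is.na(rgi)) NA else
    (max_off < max_abs_r && abs(rgi) < max_abs_r_guilt_inequity)
  structure(list(
    cor = cm, max_abs_r = max_off, r_guilt_inequity = rgi,
    bounds = c(max_abs_r = max_abs_r,
               max_abs_r_guilt_inequity = max_abs_r_guilt_inequity),
    within_bounds = within, flags = flags, n_trials = nrow(reg)
  ), class = "design_diagnostics")
}

#' @export
print.design_diagnostics <- function(x, ...) {
  cat("Design diagnostics (", x$n_trials, " trials)\n", sep = "")
  print(round(x$cor, 4))
  cat("max |r|:", format(x$max_abs_r, digits = 4),
      " r(guilt, inequity):", format(x$r_guilt_inequity, digits = 4), "\n")
  cat("within bounds:", x$within_bounds, "\n")
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

# sample one trial's six payoffs: three distinct integers per player, ordered
# so that y_A < z_A < x_A and z_B < x_B < y_B
sample_trial_payoffs <- function(n, lo, hi) {
  a <- t(replicate(n, sort(sample(lo:hi, 3L))))
  b <- t(replicate(n, sort(sample(lo:hi, 3L))))
  data.frame(
    x_A = a[, 3], x_B = b[, 2], y_A = a[, 1], y_B = b[, 3],
    z_A = a[, 2], z_B = b[, 1]
  )
}

#' Generate a trial design satisfying the orthogonality bounds
#'
#' Seeded rejection sampling: candidate 45-trial designs are drawn (integer
#' payoffs uniform on `payoff_range` subject to the two ordering chains; tau
#' schedule from [build_tau_schedule()]) until the regressor correlation
#' bounds are met. The published payoff tables are not public, so the
#' generator reproduces the design's statistical structure — valid orderings
#' and near-orthogonal Reward/Guilt/Inequity — which is what downstream
#' estimation depends on.
#'
#' @param n_trials number of trials; must equal the schedule length.
#' @param tau_counts `level -> count` table passed to [build_tau_schedule()].
#' @param payoff_range integer vector `c(lo, hi)` for all six payoffs
#'   (default 1-20 points).
#' @param max_abs_r,max_abs_r_guilt_inequity correlation bounds, as in
#'   [design_diagnostics()].
#' @param seed integer seed; the search is bit-reproducible given the seed.
#' @param max_attempts rejection-sampling budget (default 100000); exhausting
#'   it is an error naming the unmet bound, never a silent fallback.
#' @return object of class `trial_design`: a data frame with columns
#'   `trial_id, x_A, x_B, y_A, y_B, z_A, z_B, tau`, with the accepted
#'   [design_diagnostics()] in attribute `"diagnostics"` and the attempt
#'   count in `"attempts"`.
#' @export
#' @examples
#' d <- generate_design(seed = 1)
#' attr(d, "diagnostics")
generate_design <- function(n_trials = 45L,
                            tau_counts = default_tau_counts(),
                            payoff_range = c(1L, 20L),
                            max_abs_r = 0.30,
                            max_abs_r_guilt_inequity = 0.05,
                            seed = 1L,
                            max_attempts = 100000L) {
  if (diff(payoff_range) < 2L)
    stop("payoff_range must span at least 3 integers to permit valid orderings")
  tau0 <- build_tau_schedule(tau_counts, seed = NULL)
  if (length(tau0) != n_trials)
    stop("tau schedule length (", length(tau0), ") != n_trials (", n_trials, ")")
  with_seed(seed, {
    last <- NULL
    for (attempt in seq_len(max_attempts)) {
      pay <- sample_trial_payoffs(n_trials, payoff_range[1], payoff_range[2])
      design <- cbind(trial_id = seq_len(n_trials), pay, tau = sample(tau0))
      diag <- design_diagnostics(design, max_abs_r, max_abs_r_guilt_inequity)
      if (isTRUE(diag$within_bounds) || is.na(diag$within_bounds)) {
        attr(design, "diagnostics") <- diag
        attr(design, "attempts") <- attempt
        class(design) <- c("trial_design", "data.frame")
        return(design)
      }
      last <- diag
    }
    stop("design search failed after ", max_attempts, " attempts; last max |r| = ",
         format(last$max_abs_r, digits = 4), ", |r(guilt, inequity)| = ",
         format(abs(last$r_guilt_inequity), digits = 4),
         " (bounds ", max_abs_r, ", ", max_abs_r_guilt_inequity, ")")
  })
}

#' Write / read a trial design as CSV
#'
#' `trials.csv` columns: `trial_id, x_A, x_B, y_A, y_B, z_A, z_B, tau`
#' (tau a fraction, written with 4 decimals), comma-delimited UTF-8 with
#' header.
#'
#' @param design a trial-design data frame.
#' @param path file path.
#' @return `write_trials` invisibly returns `path`; `read_trials` returns a
#'   validated `trial_design` data frame.
#' @export
write_trials <- function(design, path) {
  out <- as.data.frame(design)
  out$tau <- sprintf("%.4f", out$tau)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  d <- utils::read.csv(path, fileEncoding = "UTF-8")
  need <- c("trial_id", "x_A", "x_B", "y_A", "y_B", "z_A", "z_B", "tau")
  if (!all(need %in% names(d)))
    stop("trials file must have columns ", paste(need, collapse = ", "))
  if (any(d$tau < 0 | d$tau > 1)) stop("tau must be a fraction in [0, 1]")
  bad <- which(!vapply(seq_len(nrow(d)), function(i) validate_payoffs(d[i, ])$valid, logical(1)))
  if (length(bad)) stop("invalid payoff orderings in trials: ", paste(bad, collapse = ", "))
  class(d) <- c("trial_design", "data.frame")
  d
}
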