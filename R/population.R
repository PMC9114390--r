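#' Truncated-normal sampler (inverse-CDF)
#' @keywords internal
rtruncnorm <- function(n, mean = 0, sd = 1, lower = -Inf, upper = Inf) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  q <- stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
  pmin(pmax(q, lower), upper)
}

#' Configure a synthetic cohort
#'
#' Defines the generating distributions for one country's cohort:
#' covariates (gender, age, education, income, Big Five on the 1-5 BFI-10
#' scale) and latent preferences (guilt sensitivity `gamma`, inequity
#' sensitivity `alpha`, choice intercept, temperature).
#'
#' Defaults emulate the study structure this package targets: ~300
#' participants per country with 55-60% women; men with higher mean guilt
#' sensitivity (0.5 vs 0.3, SD 0.3, truncated at 0); women scoring higher
#' on neuroticism (+0.4) and agreeableness (+0.3); latent-scale covariate
#' correlations between gender and income and between income and education;
#' and a country-specific trait channel into men's guilt sensitivity —
#' conscientiousness for the "UK-like" profile, neuroticism for the
#' "KR-like" profile. Education (1-6) and income (1-10) bands, and the
#' age/income/education distributions, are package conventions: the real
#' cohorts' descriptive statistics are not public, so these are placeholders
#' with the documented qualitative structure only.
#'
#' @param country `"KR-like"` or `"UK-like"`; picks the default trait link
#'   and fraction of women (0.60 / 0.55).
#' @param n cohort size (default 300).
#' @param frac_women fraction of women; gender is coded men = 1.
#' @param gamma_mean_women,gamma_mean_men,gamma_sd guilt-sensitivity
#'   distribution by gender (normal truncated at 0).
#' @param alpha_mean,alpha_sd inequity-sensitivity distribution (truncated
#'   at 0).
#' @param trait_link which Big Five trait feeds men's guilt sensitivity
#'   (`"conscientiousness"`, `"neuroticism"`, or `"none"`).
#' @param trait_link_slope slope of that trait (centered at 3) on men's
#'   gamma, per scale point.
#' @param big5_mean,big5_sd Big Five base distribution (truncated to [1, 5]).
#' @param shift_neuroticism_women,shift_agreeableness_women additive mean
#'   shifts for women.
#' @param cor_gender_income,cor_income_education latent (Gaussian-copula)
#'   correlations among the socioeconomic covariates.
#' @param age_mean,age_sd age distribution (years, truncated to [18, 70]).
#' @param intercept_mean,intercept_sd per-participant choice-bias
#'   distribution on the log-odds scale.
#' @param temperature fixed choice temperature (default 1).
#' @return object of class `population_config` (named list).
#' @export
population_config <- function(country = c("KR-like", "UK-like"),
                              n = 300L,
                              frac_women = NULL,
                              gamma_mean_women = 0.3,
                              gamma_mean_men = 0.5,
                              gamma_sd = 0.3,
                              alpha_mean = 0.15,
                              alpha_sd = 0.1,
                              trait_link = NULL,
                              trait_link_slope = 0.15,
                              big5_mean = 3,
                              big5_sd = 0.8,
                              shift_neuroticism_women = 0.4,
                              shift_agreeableness_women = 0.3,
                              cor_gender_income = 0.25,
                              cor_income_education = 0.3,
                              age_mean = 40,
                              age_sd = 12,
                              intercept_mean = 0,
                              intercept_sd = 0.5,
                              temperature = 1) {
  country <- match.arg(country)
  if (is.null(frac_women)) frac_women <- if (country == "KR-like") 0.60 else 0.55
  if (is.null(trait_link))
    trait_link <- if (country == "KR-like") "neuroticism" else "conscientiousness"
  trait_link <- match.arg(trait_link, c("conscientiousness", "neuroticism", "none"))
  stopifnot(n >= 1, frac_women >= 0, frac_women <= 1,
            gamma_sd >= 0, alpha_sd >= 0, big5_sd >= 0, intercept_sd >= 0,
            temperature > 0)
  structure(as.list(environment()), class = "population_config")
}

#' A null population: no gender gap, homogeneous guilt sensitivity
#'
#' Convenience configuration for calibration checks of the group-level
#' Gender x Guilt test: both genders share the same mean guilt sensitivity
#' and the between-participant spread in `gamma` is zero, so the
#' random-intercept model fitted downstream is correctly specified under
#' this null. (With heterogeneous guilt slopes the Wald test is
#' anticonservative; see the methods vignette.)
#'
#' @param ... overrides passed to [population_config()].
#' @return a `population_config`.
#' @export
null_population_config <- function(...) {
  population_config(gamma_mean_women = 0.4, gamma_mean_men = 0.4,
                    gamma_sd = 0, trait_link = "none", ...)
}

#' Sample a cohort's covariates and latent preferences
#'
#' Draws participants from a [population_config()]: socioeconomic
#' covariates through a Gaussian copula (gender thresholded at the
#' configured fraction of women; income/education cut into
#' equal-probability ordinal bands), Big Five scores as truncated normals
#' on [1, 5] with the configured gender shifts, and the hidden preference
#' truth table (`gamma`, `alpha`, intercept, temperature) with the
#' configured gender gap and gender x trait link. The truth table is kept
#' separate from the "observed" covariates so downstream estimation can be
#' validated against it.
#'
#' @param cfg a [population_config()].
#' @param seed integer seed (sampling is deterministic given the seed).
#' @param pid_prefix prefix for participant ids.
#' @return list with `participants` (pid, country, gender, age, education,
#'   income, five trait columns) and `truth` (pid, gamma, alpha, intercept,
#'   temperature).
#' @export
sample_participants <- function(cfg, seed = 1L, pid_prefix = NULL) {
  stopifnot(inherits(cfg, "population_config"))
  n <- cfg$n
  if (n <= 0) stop("cohort size must be positive")
  if (is.null(pid_prefix)) pid_prefix <- sub("-like$", "", cfg$country)
  with_seed(seed, {
    # Gaussian copula over (gender latent, income, education, age)
    R <- diag(4)
    R[1, 2] <- R[2, 1] <- cfg$cor_gender_income
    R[2, 3] <- R[3, 2] <- cfg$cor_income_education
    Z <- matrix(stats::rnorm(n * 4), n, 4) %*% chol(R)
    gender <- as.integer(Z[, 1] > stats::qnorm(cfg$frac_women)) # men = 1
    income <- as.integer(cut(stats::pnorm(Z[, 2]), breaks = seq(0, 1, length.out = 11),
                             include.lowest = TRUE))
    education <- as.integer(cut(stats::pnorm(Z[, 3]), breaks = seq(0, 1, length.out = 7),
                                include.lowest = TRUE))
    age <- round(pmin(pmax(cfg$age_mean + cfg$age_sd * Z[, 4], 18), 70))

    tr <- function(shift = 0) rtruncnorm(n, cfg$big5_mean + shift, cfg$big5_sd, 1, 5)
    big5 <- data.frame(
      neuroticism = tr(cfg$shift_neuroticism_women * (gender == 0)),
      extraversion = tr(), openness = tr(),
      agreeableness = tr(cfg$shift_agreeableness_women * (gender == 0)),
      conscientiousness = tr()
    )

    gamma_mu <- ifelse(gender == 1, cfg$gamma_mean_men, cfg$gamma_mean_women)
    if (cfg$trait_link != "none")
      gamma_mu <- gamma_mu +
        cfg$trait_link_slope * (big5[[cfg$trait_link]] - 3) * (gender == 1)
    gamma <- rtruncnorm(n, gamma_mu, cfg$gamma_sd, lower = 0)
    alpha <- rtruncnorm(n, cfg$alpha_mean, cfg$alpha_sd, lower = 0)
    intercept <- stats::rnorm(n, cfg$intercept_mean, cfg$intercept_sd)

    pid <- sprintf("%s%04d", pid_prefix, seq_len(n))
    list(
      participants = cbind(
        data.frame(pid = pid, country = cfg$country, gender = gender,
                   age = age, education = education, income = income),
        big5),
      truth = data.frame(pid = pid, gamma = gamma, alpha = alpha,
                         intercept = intercept,
                         temperature = cfg$temperature)
    )
  })
}

#' Simulate trust-game choices for a cohort
#'
#' Each participant plays every trial of the design once; the cooperate
#' probability is the combined-model [choice_probability()] at that
#' participant's hidden preferences, and choices are independent Bernoulli
#' draws.
#'
#' @param participants participant table (needs `pid`).
#' @param truth preference truth table (`pid`, `gamma`, `alpha`,
#'   `intercept`, `temperature`).
#' @param design a trial design.
#' @param seed integer seed.
#' @return data frame (`pid`, `trial_id`, `choice`) with
#'   `nrow = n_participants * n_trials`; choice 1 = cooperate.
#' @export
simulate_choices <- function(participants, truth, design, seed = 1L) {
  missing_pid <- setdiff(participants$pid, truth$pid)
  if (length(missing_pid))
    stop("no truth-table parameters for pid: ", paste(missing_pid, collapse = ", "))
  tt <- truth[match(participants$pid, truth$pid), ]
  reg <- compute_regressors(design)
  n <- nrow(tt); m <- nrow(design)
  # log-odds of cooperating: temperature * (reward + gamma*guilt + alpha*inequity) + intercept
  eta <- tt$temperature * (tcrossprod(rep(1, n), reg$reward) +
                             tcrossprod(tt$gamma, reg$guilt) +
                             tcrossprod(tt$alpha, reg$inequity_abs)) +
    tt$intercept
  pr <- stats::plogis(eta)
  with_seed(seed, {
    choice <- stats::rbinom(n * m, 1L, as.vector(t(pr))) # trial-major within pid
    data.frame(pid = rep(tt$pid, each = m),
               trial_id = rep(design$trial_id, times = n),
               choice = choice)
  })
}

#' Generate a complete synthetic study bundle
#'
#' Runs design generation, cohort sampling and choice simulation for one or
#' more countries, and (optionally) writes the cross-consistent CSV bundle
#' `trials.csv`, `participants.csv`, `truth.csv`, `choices.csv` plus a
#' `manifest.json` recording the configuration and all derived seeds.
#'
#' @param configs list of [population_config()]s (one per country).
#' @param seed master seed; stage seeds are derived with [derive_seed()].
#' @param design optional pre-built design (default: [generate_design()]
#'   under the derived design seed).
#' @param dir output directory, or `NULL` to skip writing.
#' @return object of class `study_bundle`: list with `design`,
#'   `participants`, `truth`, `choices`, `manifest` (and `dir` if written).
#' @export
generate_study <- function(configs = list(population_config("KR-like"),
                                          population_config("UK-like")),
                           seed = 1L, design = NULL, dir = NULL) {
  if (inherits(configs, "population_config")) configs <- list(configs)
  seeds <- list(design = derive_seed(seed, "design"))
  if (is.null(design)) design <- generate_design(seed = seeds$design)
  parts <- list(); truths <- list(); choices <- list()
  for (cfg in configs) {
    key <- cfg$country
    seeds[[paste0("participants:", key)]] <- derive_seed(seed, paste0("participants:", key))
    seeds[[paste0("choices:", key)]] <- derive_seed(seed, paste0("choices:", key))
    pop <- sample_participants(cfg, seed = seeds[[paste0("participants:", key)]])
    ch <- simulate_choices(pop$participants, pop$truth, design,
                           seed = seeds[[paste0("choices:", key)]])
    parts[[key]] <- pop$participants
    truths[[key]] <- pop$truth
    choices[[key]] <- ch
  }
  bundle <- list(
    design = design,
    participants = do.call(rbind, c(parts, list(make.row.names = FALSE))),
    truth = do.call(rbind, c(truths, list(make.row.names = FALSE))),
    choices = do.call(rbind, c(choices, list(make.row.names = FALSE))),
    manifest = list(
      package = "trustguilt",
      version = as.character(utils::packageVersion("trustguilt")),
      master_seed = seed, seeds = seeds,
      configs = lapply(configs, function(cfg) unclass(cfg))
    )
  )
  class(bundle) <- "study_bundle"
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_trials(bundle$design, file.path(dir, "trials.csv"))
    for (f in c("participants", "truth", "choices"))
      utils::write.csv(bundle[[f]], file.path(dir, paste0(f, ".csv")),
                       row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
    jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    bundle$dir <- dir
  }
  bundle
}

#' @export
print.study_bundle <- function(x, ...) {
  cat("Synthetic study bundle:", nrow(x$design), "trials,",
      nrow(x$participants), "participants,", nrow(x$choices), "choice records\n")
  cat("countries:", paste(unique(x$participants$country), collapse = ", "), "\n")
  if (!is.null(x$dir)) cat("written to:", x$dir, "\n")
  invisible(x)
}
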