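# shared fixtures, all generated in code

# the worked example trial used throughout the utility/regressor checks
example_trial <- function() {
  list(x_A = 12, x_B = 10, y_A = 4, y_B = 16, z_A = 8, z_B = 6, tau = 0.8)
}

# one default 45-trial design per session (generation is seeded and cheap,
# but many tests share it)
.fixture_env <- new.env(parent = emptyenv())
default_design <- function() {
  if (is.null(.fixture_env$design)) .fixture_env$design <- generate_design(seed = 1)
  .fixture_env$design
}

# random valid trials (payoff chains enforced by sorting three distinct draws)
random_trials <- function(n, seed = 1) {
  set.seed(seed)
  a <- t(replicate(n, sort(sample(1:20, 3))))
  b <- t(replicate(n, sort(sample(1:20, 3))))
  data.frame(trial_id = seq_len(n),
             x_A = a[, 3], x_B = b[, 2], y_A = a[, 1], y_B = b[, 3],
             z_A = a[, 2], z_B = b[, 1],
             tau = sample(seq(0.6, 1, by = 0.1), n, replace = TRUE))
}

# cohort of identical-parameter subjects with simulated choices joined to the
# design regressors (used by recovery and estimation tests)
homogeneous_cohort <- function(n_subj, gamma, alpha, design = default_design(),
                               intercept = 0, temperature = 1, seed = 1) {
  truth <- data.frame(pid = sprintf("S%04d", seq_len(n_subj)),
                      gamma = gamma, alpha = alpha,
                      intercept = intercept, temperature = temperature)
  parts <- data.frame(pid = truth$pid)
  choices <- simulate_choices(parts, truth, design, seed = seed)
  list(truth = truth, choices = choices,
       long = join_choices(choices, design))
}

# long-format mixed-logit data for a sampled cohort, without merge overhead
cohort_long <- function(cfg, design = default_design(), seed_pop = 1, seed_choice = 2) {
  pop <- sample_participants(cfg, seed = seed_pop)
  ch <- simulate_choices(pop$participants, pop$truth, design, seed = seed_choice)
  reg <- compute_regressors(design)
  n <- nrow(pop$participants)
  m <- nrow(design)
  long <- data.frame(
    pid = ch$pid, trial_id = ch$trial_id, choice = ch$choice,
    reward = rep(reg$reward, times = n), guilt = rep(reg$guilt, times = n),
    inequity_abs = rep(reg$inequity_abs, times = n),
    gender = rep(pop$participants$gender, each = m)
  )
  list(pop = pop, long = long)
}

mixed_formula <- choice ~ reward + guilt + inequity_abs + gender + gender:guilt
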