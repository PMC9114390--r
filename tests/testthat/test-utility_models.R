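tr <- example_trial()

test_that("utilities reproduce the hand-computed worked examples", {
  expect_equal(utility_abs(tr, agent_params(alpha = 0.3), "cooperate"), 9.4)
  expect_equal(utility_fs(tr, agent_params(phi = 0.5, omega = 0.3), "cooperate"), 9.0)
  expect_equal(utility_fs(tr, agent_params(phi = 0.5, omega = 0.3), "defect"), 12.4)
  a <- agent_params(gamma = 0.5, alpha = 0.1)
  expect_equal(utility_combined(tr, a, "cooperate"), 9.8)
  expect_equal(utility_combined(tr, a, "defect"), 11.6)
})

test_that("selfish and zero-inequity special cases reduce to raw payoffs", {
  selfish <- agent_params()
  expect_equal(utility_abs(tr, selfish, "cooperate"), tr$x_B)
  expect_equal(utility_combined(tr, selfish, "defect"), tr$y_B)
  # equal payoffs: inequity term cannot bind for any alpha
  even <- list(x_A = 10, x_B = 10, y_A = 4, y_B = 16, tau = 0.8)
  expect_equal(utility_abs(even, agent_params(alpha = 5), "cooperate"), 10)
  # zero belief kills the guilt term
  tr0 <- tr; tr0$tau <- 0
  a <- agent_params(gamma = 2, alpha = 0.3)
  expect_equal(utility_combined(tr0, a, "defect"), utility_abs(tr0, a, "defect"))
})

test_that("Fehr-Schmidt collapses to the absolute model when phi = omega = alpha", {
  trials <- random_trials(100, seed = 11)
  for (s in c(0, 0.2, 0.7)) {
    a <- agent_params(alpha = s, phi = s, omega = s)
    expect_equal(utility_fs(trials, a, "cooperate"), utility_abs(trials, a, "cooperate"))
    expect_equal(utility_fs(trials, a, "defect"), utility_abs(trials, a, "defect"))
  }
})

test_that("Player B has no utility at the outside option", {
  expect_error(utility_abs(tr, agent_params(), "Z"), "no move")
  expect_error(utility_fs(tr, agent_params(), "Z"), "no move")
  expect_error(utility_combined(tr, agent_params(), "Z"), "no move")
})

test_that("deterministic guilt-averse choice follows the strict inequality", {
  expect_equal(cooperate_deterministic(tr, 1.0), "cooperate") # 16 - 6.4 < 10
  expect_equal(cooperate_deterministic(tr, 0.9), "defect")    # 16 - 5.76 >= 10
  # exact indifference (gamma = 6 / 6.4) resolves to defect
  expect_equal(cooperate_deterministic(tr, 0.9375), "defect")
})

test_that("deterministic choice agrees with the combined-utility sign at alpha = 0", {
  trials <- random_trials(150, seed = 12)
  for (g in c(0, 0.5, 1, 2)) {
    a <- agent_params(gamma = g)
    diff <- utility_combined(trials, a, "cooperate") - utility_combined(trials, a, "defect")
    expect_identical(cooperate_deterministic(trials, g),
                     ifelse(diff > 0, "cooperate", "defect"))
  }
})

test_that("choice probability matches the logistic of the utility difference", {
  # tied utilities, no bias: exactly 1/2
  even <- list(x_A = 5, x_B = 8, y_A = 5, y_B = 8, tau = 0.7)
  expect_equal(choice_probability(even, agent_params(), "combined"), 0.5)
  # worked example: difference = -6 + 6.4 = 0.4
  expect_equal(choice_probability(tr, agent_params(gamma = 1), "combined"),
               plogis(0.4), tolerance = 1e-12)
  expect_equal(round(choice_probability(tr, agent_params(gamma = 1), "combined"), 4),
               0.5987)
})

test_that("cooperation probability is monotone in gamma and in tau", {
  trials <- random_trials(50, seed = 13)
  gammas <- seq(0, 3, by = 0.25)
  p_by_gamma <- sapply(gammas, function(g)
    choice_probability(trials, agent_params(gamma = g, alpha = 0.2), "combined"))
  expect_true(all(diff(t(p_by_gamma)) >= 0))
  taus <- seq(0, 1, by = 0.1)
  p_by_tau <- sapply(taus, function(tt) {
    trials2 <- trials; trials2$tau <- tt
    choice_probability(trials2, agent_params(gamma = 0.8, alpha = 0.2), "combined")
  })
  expect_true(all(diff(t(p_by_tau)) >= 0))
  # and the monotone limit: gamma large forces cooperation
  expect_true(all(choice_probability(trials, agent_params(gamma = 50), "combined") > 0.999))
})

test_that("combined-model log-odds decompose exactly into the regressors", {
  trials <- random_trials(200, seed = 14)
  reg <- compute_regressors(trials)
  set.seed(15)
  for (i in 1:10) {
    g <- runif(1, 0, 1.5); al <- runif(1, 0, 0.6)
    a <- agent_params(gamma = g, alpha = al)
    logodds <- utility_combined(trials, a, "cooperate") -
      utility_combined(trials, a, "defect")
    expect_equal(logodds, reg$reward + g * reg$guilt + al * reg$inequity_abs,
                 tolerance = 1e-12)
    # and the stochastic-choice rule is the logistic of that difference
    expect_equal(choice_probability(trials, a, "combined"), plogis(logodds),
                 tolerance = 1e-12)
  }
  # same identity for the FS specification and its two inequity components
  a <- agent_params(gamma = 0.4, phi = 0.5, omega = 0.2)
  logodds_fs <- utility_fs(trials, a, "cooperate") - utility_fs(trials, a, "defect")
  expect_equal(logodds_fs,
               reg$reward + 0.5 * reg$inequity_disadv + 0.2 * reg$inequity_adv,
               tolerance = 1e-12)
})

test_that("temperature and intercept enter the choice rule as documented", {
  a <- agent_params(gamma = 1, temperature = 2, intercept = -0.5)
  expect_equal(choice_probability(tr, a, "combined"), plogis(2 * 0.4 - 0.5),
               tolerance = 1e-12)
  expect_error(agent_params(temperature = 0))
  expect_error(agent_params(gamma = -0.1))
})
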