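test_that("cohort sampling is deterministic and respects the documented ranges", {
  cfg <- population_config("KR-like", n = 200)
  a <- sample_participants(cfg, seed = 41)
  b <- sample_participants(cfg, seed = 41)
  expect_identical(a, b)
  p <- a$participants
  expect_true(all(p$gender %in% 0:1))
  big5 <- c("neuroticism", "extraversion", "openness", "agreeableness",
            "conscientiousness")
  for (v in big5) expect_true(all(p[[v]] >= 1 & p[[v]] <= 5))
  expect_true(all(p$education %in% 1:6))
  expect_true(all(p$income %in% 1:10))
  expect_true(all(p$age >= 18 & p$age <= 70))
  expect_true(all(a$truth$gamma >= 0))
  expect_true(all(a$truth$alpha >= 0))
  # truth stays separate from the observed covariates
  expect_false(any(c("gamma", "alpha") %in% names(p)))
})

test_that("configured population structure shows up at large n", {
  cfg <- population_config("UK-like", n = 4000)
  s <- sample_participants(cfg, seed = 42)
  p <- s$participants; tt <- s$truth
  men <- p$gender == 1
  # gender gap in guilt sensitivity
  expect_gt(mean(tt$gamma[men]), mean(tt$gamma[!men]))
  # women higher on neuroticism and agreeableness
  expect_gt(mean(p$neuroticism[!men]), mean(p$neuroticism[men]))
  expect_gt(mean(p$agreeableness[!men]), mean(p$agreeableness[men]))
  # UK-like: conscientiousness feeds men's gamma, not women's
  expect_gt(cor(p$conscientiousness[men], tt$gamma[men]),
            cor(p$conscientiousness[!men], tt$gamma[!men]))
  # latent socioeconomic correlations carry through the copula
  expect_gt(cor(p$gender, p$income), 0.1)
  expect_gt(cor(p$income, p$education), 0.15)
})

test_that("a null configuration removes the gender gap in expectation", {
  cfg <- null_population_config(n = 4000)
  s <- sample_participants(cfg, seed = 43)
  men <- s$participants$gender == 1
  expect_equal(mean(s$truth$gamma[men]), mean(s$truth$gamma[!men]),
               tolerance = 0.02)
})

test_that("choice simulation conserves records and keys", {
  d <- default_design()
  cfg <- population_config("KR-like", n = 30)
  s <- sample_participants(cfg, seed = 44)
  ch <- simulate_choices(s$participants, s$truth, d, seed = 45)
  expect_equal(nrow(ch), 30 * 45)
  expect_false(anyDuplicated(ch[c("pid", "trial_id")]) > 0)
  expect_true(all(ch$trial_id %in% d$trial_id))
  expect_true(all(ch$choice %in% 0:1))
  expect_identical(ch, simulate_choices(s$participants, s$truth, d, seed = 45))
  # a participant without truth parameters is named in the error
  expect_error(simulate_choices(rbind(s$participants,
                                      transform(s$participants[1, ], pid = "ghost")),
                                s$truth, d, seed = 1), "ghost")
})

test_that("preference-free agents behave as the utility model dictates", {
  d <- default_design()
  # gamma = alpha = 0 at high temperature: reward < 0 forces defection
  truth <- data.frame(pid = "selfish", gamma = 0, alpha = 0, intercept = 0,
                      temperature = 50)
  ch <- simulate_choices(data.frame(pid = "selfish"), truth, d, seed = 46)
  expect_true(all(ch$choice == 0))
  # tied utilities: cooperation rate ~ 1/2 over many draws
  tied <- data.frame(trial_id = 1:45, x_A = 5, x_B = 8, y_A = 5, y_B = 8,
                     z_A = 5, z_B = 5, tau = 0.8)
  truth2 <- data.frame(pid = sprintf("T%02d", 1:40), gamma = 0.7, alpha = 0.3,
                       intercept = 0, temperature = 1)
  ch2 <- simulate_choices(data.frame(pid = truth2$pid), truth2, tied, seed = 47)
  expect_equal(mean(ch2$choice), 0.5, tolerance = 0.05)
})

test_that("men cooperate more than women under the default gender gap", {
  d <- default_design()
  cfg <- population_config("KR-like", n = 400)
  s <- sample_participants(cfg, seed = 48)
  ch <- simulate_choices(s$participants, s$truth, d, seed = 49)
  rate <- tapply(ch$choice, ch$pid, mean)
  men <- s$participants$pid[s$participants$gender == 1]
  expect_gt(mean(rate[names(rate) %in% men]),
            mean(rate[!(names(rate) %in% men)]))
})

test_that("study bundles are cross-consistent and byte-identical given the seed", {
  cfgs <- list(population_config("KR-like", n = 8),
               population_config("UK-like", n = 8))
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  b1 <- generate_study(cfgs, seed = 50, dir = dir1)
  b2 <- generate_study(cfgs, seed = 50, dir = dir2)
  files <- c("trials.csv", "participants.csv", "truth.csv", "choices.csv",
             "manifest.json")
  for (f in files) {
    expect_true(file.exists(file.path(dir1, f)))
    expect_identical(readLines(file.path(dir1, f)), readLines(file.path(dir2, f)))
  }
  expect_equal(nrow(b1$participants), 16)
  expect_equal(nrow(b1$choices), 16 * 45)
  # foreign keys resolve
  expect_true(all(b1$choices$pid %in% b1$participants$pid))
  expect_true(all(b1$participants$pid %in% b1$truth$pid))
  expect_true(all(b1$choices$trial_id %in% b1$design$trial_id))
  # minimal bundle parses end to end
  tiny <- generate_study(list(population_config("KR-like", n = 1)), seed = 51)
  expect_equal(nrow(tiny$choices), 45)
})
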