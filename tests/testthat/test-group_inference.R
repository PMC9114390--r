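# small fitted cohort shared by the group-level tests
group_fixture <- local({
  env <- new.env()
  function() {
    if (is.null(env$out)) {
      d <- default_design()
      cfg <- population_config("UK-like", n = 150)
      pop <- sample_participants(cfg, seed = 61)
      ch <- simulate_choices(pop$participants, pop$truth, d, seed = 62)
      env$out <- list(pop = pop, fits = batch_fit(ch, d, pop$participants))
    }
    env$out
  }
})

test_that("group tables carry 9 or 17 predictors as specified", {
  gf <- group_fixture()
  t1 <- build_group_table(gf$fits, gf$pop$participants)
  expect_length(attr(t1, "predictors"), 9)
  t2 <- build_group_table(gf$fits, gf$pop$participants, with_interactions = TRUE)
  expect_length(attr(t2, "predictors"), 17)
  expect_true(all(paste0("gender_x_",
                         c("neuroticism", "extraversion", "openness",
                           "agreeableness", "conscientiousness", "age",
                           "education", "income")) %in% names(t2)))
  # raw product definition
  expect_equal(t2$gender_x_age, t2$gender * t2$age)
  # centered variant
  t2c <- build_group_table(gf$fits, gf$pop$participants, with_interactions = TRUE,
                           center_interactions = TRUE)
  expect_equal(t2c$gender_x_age, t2c$gender * (t2c$age - mean(t2c$age)))
})

test_that("degenerate cohorts and broken joins are caught", {
  gf <- group_fixture()
  women <- gf$pop$participants[gf$pop$participants$gender == 0, ]
  fits_w <- gf$fits$fits[gf$fits$fits$pid %in% women$pid, ]
  tw <- build_group_table(fits_w, women, with_interactions = TRUE)
  const <- attr(tw, "constant_columns")
  expect_true("gender" %in% const)
  expect_true(all(grepl("gender", const)))
  expect_error(build_group_table(gf$fits, gf$pop$participants[-1, ]), "pid")
  expect_error(build_group_table(gf$fits, gf$pop$participants[, -4]),
               "lacks covariates: age")
})

test_that("the unpenalized limit of the lasso is ordinary least squares", {
  set.seed(63)
  n <- 60
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("v", 1:5)))
  y <- drop(X %*% c(1, -2, 0, 0.5, 3)) + rnorm(n)
  co <- lasso_at(X, y, lambda = 0)
  expect_equal(unname(drop(co)), unname(coef(lm(y ~ X))), tolerance = 1e-6)
})

test_that("a single-predictor lasso reproduces the soft-threshold closed form", {
  set.seed(64)
  n <- 50
  x <- rnorm(n); x <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  y <- 2 * x # OLS coefficient exactly 2, y centered
  # glmnet needs a second column; one exactly orthogonal to x and y leaves
  # the solution unchanged (its KKT condition holds with subgradient 0)
  z <- rnorm(n); z <- z - mean(z); z <- z - x * mean(z * x)
  z <- z / sqrt(mean(z^2))
  co <- lasso_at(cbind(x = x, z = z), y, lambda = 0.5)
  expect_equal(co["x", 1], 1.5, tolerance = 1e-8)
  expect_equal(co["z", 1], 0)
  # shrinkage path: larger penalties shrink all the way to zero
  co2 <- lasso_at(cbind(x = x, z = z), y, lambda = c(2.5, 1, 0.5))
  expect_equal(unname(co2["x", ]), c(0, 1, 1.5), tolerance = 1e-8)
})

test_that("cross-validated lasso solutions satisfy the KKT conditions", {
  gf <- group_fixture()
  for (inter in c(FALSE, TRUE)) {
    tab <- build_group_table(gf$fits, gf$pop$participants,
                             with_interactions = inter)
    fit <- cv_lasso(tab, seed = 65)
    xy <- trustguilt:::group_xy(tab)
    kkt <- lasso_kkt(xy$x, xy$y, fit$coefficients, fit$chosen_lambda)
    expect_lt(max(kkt), 1e-6)
  }
})

test_that("cross-validation is deterministic given the seed", {
  gf <- group_fixture()
  tab <- build_group_table(gf$fits, gf$pop$participants)
  f1 <- cv_lasso(tab, seed = 66)
  f2 <- cv_lasso(tab, seed = 66)
  expect_identical(f1$chosen_lambda, f2$chosen_lambda)
  expect_identical(f1$coefficients, f2$coefficients)
  # the one-standard-error rule never picks a smaller penalty than the minimum
  f3 <- cv_lasso(tab, seed = 66, lambda_rule = "1se")
  expect_gte(f3$chosen_lambda, f1$chosen_lambda)
})

test_that("lasso input contracts are enforced", {
  gf <- group_fixture()
  tab <- build_group_table(gf$fits, gf$pop$participants)
  expect_error(cv_lasso(tab[1:8, ], folds = 10), "folds")
  const <- tab; const$beta_guilt <- 1
  expect_error(cv_lasso(const), "constant")
})

test_that("the gender effect dominates the specification-(1) lasso", {
  gf <- group_fixture()
  tab <- build_group_table(gf$fits, gf$pop$participants)
  fit <- cv_lasso(tab, seed = 67)
  co <- fit$coefficients[setdiff(names(fit$coefficients), "(Intercept)")]
  expect_equal(names(which.max(abs(co))), "gender")
  expect_gt(co[["gender"]], 0)
})

test_that("OLS cross-check is exact on clean designs and loud on collinear ones", {
  gf <- group_fixture()
  tab <- build_group_table(gf$fits, gf$pop$participants)
  # noiseless linear target: coefficients recovered exactly, residuals 0
  tab2 <- tab
  tab2$beta_guilt <- 0.1 + 0.3 * tab2$gender + 0.05 * tab2$conscientiousness
  f <- suppressWarnings(fit_ols(tab2)) # summary.lm warns on a perfect fit
  expect_equal(unname(coef(f)[c("gender", "conscientiousness")]), c(0.3, 0.05),
               tolerance = 1e-10)
  expect_lt(f$sigma, 1e-10)
  # orthonormal centered predictors: coefficients are inner products with the target
  set.seed(68)
  Q <- qr.Q(qr(scale(matrix(rnorm(50 * 3), 50, 3), scale = FALSE)))
  yq <- rnorm(50)
  orth <- data.frame(pid = seq_len(50), beta_guilt = yq,
                     q1 = Q[, 1], q2 = Q[, 2], q3 = Q[, 3])
  class(orth) <- c("group_table", "data.frame")
  fo <- fit_ols(orth)
  expect_equal(unname(coef(fo)[c("q1", "q2", "q3")]), drop(crossprod(Q, yq)),
               tolerance = 1e-10)
  # duplicated column: error names the aliased columns
  dup <- tab
  dup$income2 <- dup$income
  attr(dup, "predictors") <- c(attr(tab, "predictors"), "income2")
  expect_error(fit_ols(dup), "collinear columns: income2")
})
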