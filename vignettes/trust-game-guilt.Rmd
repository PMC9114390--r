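---
title: "Guilt aversion in binary trust games: models, simulation and estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Guilt aversion in binary trust games: models, simulation and estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The game and the psychological model

The task is a sequential two-player trust game. Player A chooses between an
outside option `Z` (payoffs `z_A`, `z_B`) and trusting (`W`); after trust,
Player B chooses Cooperate (payoffs `x_A`, `x_B`) or Defect (`y_A`, `y_B`).
Two strict payoff chains define the dilemma: `y_A < z_A < x_A` (trust is a
gamble for A) and `z_B < x_B < y_B` (defection pays for B). A also states a
belief `tau`, the probability that B will cooperate.

Belief-dependent guilt aversion says B suffers when letting A down relative
to what A expects. If B defects, A receives `y_A` instead of the
`tau * x_A + (1 - tau) * y_A` A expects; the shortfall `tau * (x_A - y_A)` is
the amount of guilt. With guilt sensitivity `gamma >= 0` a purely guilt-averse
B cooperates iff

    y_B - gamma * tau * (x_A - y_A) < x_B   (strict; ties resolve to Defect,
                                             matching the strict inequality)

Three utility specifications for B are implemented (`utility_abs`,
`utility_fs`, `utility_combined`): absolute-difference inequity aversion
(one sensitivity `alpha`), the Fehr–Schmidt form (separate sensitivities
`phi`, `omega` for disadvantageous and advantageous inequality), and the
combined guilt + absolute-inequity model. All sensitivities are
role-dependent: only the second mover carries them, since only the second
mover can disappoint a trusting partner.

Choices are stochastic: `P(cooperate) = plogis(temperature * (u_C - u_D) +
intercept)`. The reduced-form logistic regression

    logit P = b0 + b1*Reward + b2*Guilt + b3*Inequity
    Reward = x_B - y_B,  Guilt = tau*(x_A - y_A),
    Inequity = -(|x_A - x_B| - |y_A - y_B|)

is an exact reparametrization of the combined model: `b1 = temperature`,
`b2/b1 = gamma`, `b3/b1 = alpha`, `b0 = intercept`. The temperature and
intercept are not separate claims about behavior — a logistic fit cannot
distinguish utility scale from choice noise — but they make simulated agents
realistic: the default generator gives every participant `temperature = 1`
and a personal intercept drawn with SD 0.5 on the log-odds scale, which is
exactly the heterogeneity the downstream random-intercept model assumes.

## Task designs

`generate_design()` draws 45 integer payoff tables on 1–20 points (three
distinct sorted values per player per trial, which enforces both strict
chains) and assigns the fixed belief schedule — 60% x7, 70% x5, 80% x13,
90% x11, 100% x9; `tau` is stored as a fraction and only converted at I/O
boundaries. Candidate designs are rejected until all pairwise Pearson
correlations among Reward/Guilt/Inequity are below 0.30 and
`|r(Guilt, Inequity)| < 0.05` (Pearson is used throughout; the bound pair
mirrors the published design's orthogonality target). Rejection sampling has
a loud failure after `max_attempts` (default 100,000) candidates; under the
default payoff range acceptance takes a handful of attempts. Given a seed
the search is bit-reproducible.

The schedule floor of 60% reflects the task logic: a first mover with a low
stated belief would not plausibly have trusted, so second movers only face
high-trust scenarios.

## What the synthetic cohorts emulate — and what they do not

`population_config()` describes one country's cohort. Defaults: n = 300,
55–60% women (KR-like 60%, UK-like 55%), guilt sensitivity truncated-normal
at zero with women mean 0.3 / men mean 0.5 / SD 0.3, inequity sensitivity
mean 0.15 / SD 0.1. These preference values were chosen once so that
simulated cooperation rates sit in a realistic interior range (roughly
0.3–0.6 by gender) — no preference distributions are published for the real
cohorts. Big Five scores are truncated normals on the 1–5 BFI-10 scale
(mean 3, SD 0.8) with women shifted +0.4 on neuroticism and +0.3 on
agreeableness, matching the standard direction of gender differences in the
trait literature. Socioeconomic covariates run through a Gaussian copula
with latent correlations 0.25 (gender–income) and 0.30 (income–education);
education (6 bands), income (10 bands) and the age distribution
(N(40, 12²) truncated to 18–70) are package conventions — placeholders,
since the real cohorts' descriptive statistics are not public.

Each country has one trait channel into men's guilt sensitivity:
`gamma += 0.15 * (trait - 3)` for men only, with trait = conscientiousness
(UK-like) or neuroticism (KR-like). The slope 0.15 per scale point is a
design choice: across a typical ±1.5-point trait range it moves `gamma` by
about as much as the 0.2 gender gap itself, large enough to be recoverable
at n = 300 yet far from dominant.

Passing tests on these cohorts shows the *pipeline* recovers structure that
is truly there; it cannot show that real populations have that structure.
The generator also deliberately omits: dropout, item-level BFI-10 responses,
trial-order effects, within-session learning, and any model of Player A.

## Per-participant estimation

Each participant's 45 choices are regressed on the trial regressors by
bias-reduced (Firth) logistic regression: Newton iteration on the
Jeffreys-prior-penalized score, step-halving on penalized-likelihood
decrease, convergence at penalized-score max-norm 1e-8 or 100 iterations.
The penalty keeps estimates finite for participants who always (or never)
cooperate — about the only realistic choice at 45 trials per person. The
intercept-only closed form `p = (y + 1/2) / (n + 1)` and brute-force
maximization of the penalized likelihood serve as test oracles.

BIC is `-2 * loglik + k * log(45)` with the *unpenalized* log-likelihood
evaluated at the bias-reduced estimate (the penalized variant is available
via `bic_likelihood = "penalized"`); using the unpenalized value keeps the
criterion comparable across models with standard asymptotics. The two
inequity specifications — `choice ~ reward + guilt + inequity_abs` (k = 4)
versus `choice ~ reward + guilt + inequity_disadv + inequity_adv` (k = 5) —
are compared per participant; ties select the absolute-difference model
(one fewer parameter). Both models keep the Guilt regressor, so they differ
only in the inequity terms.

One identifiability fact shapes these comparisons. Algebraically,

    inequity_disadv - inequity_adv = reward - (x_A - y_A)

and Guilt = `tau * (x_A - y_A)`, so the direction that separates the
Fehr–Schmidt split from the absolute model is close to a linear combination
of Reward and Guilt; only the variation of `tau` over [0.6, 1] breaks the
collinearity. At 45 trials the extra Fehr–Schmidt parameter therefore almost
never earns its BIC penalty — which is why the absolute model wins for the
overwhelming majority of simulated participants — and even data generated
with strongly asymmetric inequity preferences need on the order of 2,000+
trials (and interior choice probabilities) before BIC reliably selects the
Fehr–Schmidt form. The test suite checks exactly that, with the design
repeated 50 times.

Parameter recovery is validated on 500 simulated subjects with
`gamma = 0.6`, `alpha = 0.2`, temperature 1: the ratios of group-mean
coefficients `mean(b2)/mean(b1)` and `mean(b3)/mean(b1)` recover `gamma` and
`alpha` within ±10%. Ratios of means are used rather than means of
per-subject ratios: a subject's `b1` can sit near zero at 45 trials, making
individual ratios heavy-tailed.

## Group-level inference

**Mixed logit.** `fit_mixed_logit()` maximizes the marginal likelihood of a
logistic model with a Gaussian per-participant intercept, integrated by
*non-adaptive* Gauss–Hermite quadrature (8 nodes by default, configurable;
nodes and weights from the Golub–Welsch eigen decomposition), with an
analytic gradient and L-BFGS-B under `sigma >= 0`. Standard errors come
from the numerical Hessian at the optimum; if `sigma` sits on the boundary
the fixed-effects block is inverted alone. The default group model is
`choice ~ reward + guilt + inequity_abs + gender + gender:guilt`, the test
of whether men respond more strongly to guilt. McFadden's R² is reported
against an intercept-only ordinary logistic null (the null needs no random
intercept: with no covariates the marginal mean fully determines the
likelihood bound used for the ratio). Quadrature accuracy is tested against
brute-force trapezoid integration on toy data and against an
adaptive-quadrature reference fit (lme4) on an intercept-heterogeneous
cohort; non-adaptive quadrature degrades when the random-effect SD is large
relative to node spacing, so node counts can be raised where that matters.

A calibration caveat worth stating plainly: the generator's default
population has between-participant spread in `gamma` (SD 0.3), i.e. random
*slopes* on Guilt, which the random-intercept model does not absorb. The
Wald test for Gender × Guilt is then anticonservative — its SE omits the
dominant between-participant variance component. The type-I-error check in
the test suite therefore uses a null population with the gender gap *and*
the guilt-sensitivity spread set to zero (intercept and inequity
heterogeneity retained), verifying 5% ± 2 points over 500 replicate cohorts
of 80 participants: it validates the test where the model is correctly
specified. Against heterogeneous populations the same caveat applies to any
random-intercept-only analysis of this design; the power this buys is why
the Gender × Guilt effect is significant in essentially all replicates at
n = 300.

**Lasso.** `cv_lasso()` regresses each participant's estimated `b2`
(beta(Guilt), from the absolute-model fit) on 9 predictors (gender, five
traits, age, education, income) or 17 (adding gender × each covariate).
The solver is glmnet's coordinate descent on
`(1/2n) RSS + lambda * sum|beta_j|` with internal standardization,
coefficients reported on the original scale, unpenalized intercept, seeded
ten-fold assignment, and `lambda` at minimum CV error by default (the
one-standard-error rule via `lambda_rule = "1se"`); the choice of rule is
genuinely open, and "min" was picked as the less aggressive default for a
screening analysis. Solutions are verified against the single-predictor
soft-threshold closed form and the KKT stationarity conditions.

Interaction columns use the raw gender × covariate product by default (a
centering flag exists). Raw products are strongly collinear with the gender
main effect, and the lasso responds by loading the gender difference onto
whichever column of the bundle predicts best — typically zeroing the gender
main effect in the 17-predictor specification and keeping the configured
gender × trait column. That is a property of penalized selection under
collinearity, not a bug, and it is the reason the unpenalized OLS
cross-check (`fit_ols()`) refuses rank-deficient designs loudly instead of
dropping columns.

**Sample-size rule.** `sample_size_floor(17, 10) = 170` implements the
events-per-variable convention used to set recruitment targets for such
regressions.

## The full pipeline and problem sizes

`run_full_study()` chains design → cohorts → choices → subject fits → model
selection → mixed logit → both lasso specifications → OLS cross-check, per
country, with every stage seed derived from one master seed
(`derive_seed()`, a documented affine hash mod 2^31 − 1). Degenerate runs
(e.g. 2 participants) flag group stages as "insufficient n" rather than
failing. All artifacts (CSV bundle, report.json) are written so that every
reported number can be recomputed from them; regenerating with the same
seed reproduces the files byte for byte.

Default problem sizes were chosen to keep the full validation suite at
desk scale: the study runs two cohorts of 300; recovery uses 500 subjects;
the replicate checks use 100 cohorts of 300 (power) and 500 cohorts of 80
(calibration). The replicate loops relax the optimizer's `factr` to 1e7,
which changes coefficients at the fourth decimal — far below the scale that
a 5% rejection decision responds to.

## Known limitations

* Non-adaptive quadrature is faithful to the classic approach for this
  model class but loses accuracy at large random-effect SDs; raise `nodes`
  when `sigma` exceeds ~1.5.
* The Fehr–Schmidt split is near-unidentified within this task design (see
  above); per-subject model selection at 45 trials mostly reflects the BIC
  complexity penalty, and that is the intended reading.
* Covariate distributions (age, education, income bands) are invented
  conventions; conclusions about real cohorts require real covariates.
* The Wald Gender × Guilt test inherits the random-intercept model's
  blindness to slope heterogeneity; treat its p-values as conditional on
  that specification.
* Player A's behavior (trust/opt-out, stated beliefs) is not modeled; the
  belief schedule is experimenter-controlled, as in the task this package
  emulates.
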