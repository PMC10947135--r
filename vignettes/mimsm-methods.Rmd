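---
title: "Handling missing outcomes and confounders in marginal structural models: methods and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Handling missing outcomes and confounders in marginal structural models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Comparative effectiveness studies of treatments sustained over time face
two entangled obstacles. First, *time-varying confounding*: a patient's
evolving disease state influences both the next treatment decision and
the outcome, and is itself affected by earlier treatment, so
conventional regression adjustment blocks part of the effect it is
trying to estimate. Second, *missing data*: outcomes and time-varying
covariates collected through follow-up questionnaires go missing — some
patients drop out for good (monotone missingness), others skip
questionnaires or items intermittently (non-monotone missingness), in
the outcome, the covariates, or both at once.

`mimsm` implements and compares the two standard strategies for the
missing-data part while handling confounding by inverse probability of
treatment weighting (IPTW) in both:

* the **weighting (IPW) approach** — censor each person at their first
  missing observation, model the probability of remaining observed, and
  multiply inverse-probability-of-missingness weights (IPMW) into the
  treatment weights; and
* the **imputation (MI) approach** — multiply impute the missing cells
  by chained equations, run the weighted analysis in every completed
  dataset, and pool with Rubin's rules.

## Model and estimand

Persons $i = 1, \dots, n$ are observed at visits $t = 0, \dots, 4$ with
binary treatment $A_t$ (with $A_0 \equiv 0$: everyone starts
untreated), a continuous time-varying confounder $X_t$, a continuous
outcome $Y_t$, and baseline covariates $B = (B_{\mathrm{bin}},
B_{\mathrm{cont}})$. The marginal structural model (MSM) for the
potential outcome at the end of follow-up under a treatment history
$\bar a$ is

$$E[Y_4^{\bar a} \mid B] = \alpha + \sum_{t=1}^{4} \beta_t a_t + \gamma'B,$$

and the estimand is the always-vs-never contrast
$\mathrm{ATE} = \sum_t \beta_t$, the difference in mean end-of-follow-up
outcome between "always treat" ($a_t = 1$ for all $t \ge 1$) and "never
treat". The MSM is fitted by weighted least squares with each person's
cumulative stabilized weight

$$SW = \prod_{t=1}^{4}
  \frac{P(A_t \mid A_{t-1}, B)}{P(A_t \mid A_{t-1}, X_t, Y_{t-1}, B)},$$

both probability models being pooled logistic regressions with visit
indicators. Under the usual identification conditions (no interference,
positivity, consistency, no unmeasured confounding — all of which hold
in the generator by construction) the weighted fit recovers the causal
coefficients.

Two specification points deserve emphasis:

* **Baseline covariates appear in the MSM.** Because the stabilization
  numerator conditions on $B$, the reweighted population retains the
  dependence of treatment on $B$; the weighted outcome model must
  therefore condition on $B$ as well, else baseline confounding
  re-enters. With no treatment-baseline effect modification this leaves
  the $\beta_t$ and their sum unchanged in expectation. A large-sample
  check (n = 100{,}000) gives $\sum\hat\beta_t = 0.1996$ with $B$ in the
  model versus $-0.196$ without, against a truth of $0.2$ — the
  difference is not a subtlety. `fit_msm(baseline = TRUE)` is the
  default.
* **The outcome entering the treatment model is the previous visit's.**
  Within a visit the causal order is $X_t \to A_t \to Y_t$, so the
  outcome available at the treatment decision is $Y_{t-1}$; the weight
  denominator conditions on exactly the information the generator uses.

Robust (sandwich, HC0) standard errors are reported; with one row per
person at the final visit these coincide with id-clustered ones. For
case-study-style analyses `bootstrap_ci()` provides percentile
intervals from person-level resampling; it is deliberately not used
inside the simulation harness, where performance is judged from
replication spread.

## The weighting approach in detail

Non-monotone missingness has no generally agreed IPMW construction, so
the implementation takes the pragmatic route of treating every pattern
as monotone: `censor_after_first_missing()` discards everything from
the first visit with a missing outcome *or* confounder onward. On the
monotonized data the two observation indicators coincide, and a single
discrete-time hazard of remaining observed is modelled among those
observed at the previous visit — denominator conditioning on
$(A_{t-1}, Y_{t-1}, X_{t-1}, B)$, numerator on $(A_{t-1}, B)$, both
with visit indicators. The total weight is the product of the
stabilized treatment and missingness weights; only persons observed
through the final visit contribute to the MSM. This is exactly why the
approach pays a price under intermittent missingness: a person with a
single skipped questionnaire at visit 1 loses all their later data, and
the surviving complete cases carry increasingly variable weights.

If a panel has no missing cells the missingness models are degenerate
(observation probability one), the total weights reduce to the
treatment weights, and the IPW and MI pipelines return identical
estimates — a useful end-to-end consistency check that the test suite
asserts exactly.

## The imputation approach in detail

`mice_run()` imputes in *wide* format (one row per person, columns
$x_0..x_4$, $y_0..y_4$, $a_1..a_4$, $B$), so measurements both before
and after a missing cell inform its imputation — standard practice for
longitudinal MI. Each incomplete variable is visited cyclically:

1. regress it on the predictor set among the originally observed cases;
2. perturb the parameters — $\sigma^{2*} = \hat\sigma^2 (n_{obs}-k)/g$
   with $g \sim \chi^2_{n_{obs}-k}$, then
   $\beta^* \sim N(\hat\beta, \sigma^{2*}(X'X)^{-1})$ — so the
   imputations are *proper* (they propagate estimation uncertainty);
3. fill the missing cells from the implied predictive distribution:
   normal draws $\beta^{*\prime}x + \varepsilon^*$ for linear
   imputation, Bernoulli draws on the logistic scale for binary
   variables, or a donor's observed value under predictive mean
   matching (PMM);
4. repeat over `n_iter` cycles, and independently `M` times.

PMM picks, for each missing case, the `q = 5` observed cases whose
predicted means $\beta^{*\prime}x$ are closest (ties at the fifth
distance all included) and donates one of their observed responses at
random. Imputed values are then always elements of the observed
support, which is what makes PMM robust to a skewed outcome: linear
imputation draws symmetric noise and erases the skew.

The analysis model — treatment models, stabilized weights, weighted MSM
— is refitted within each completed dataset, and the $M$ ATE estimates
are pooled as $\hat\theta = \bar\theta_m$,
$V = W + (1 + 1/M)B$ with $W$ the mean within-imputation variance and
$B$ the between-imputation variance. Weights are estimated after
imputation, within each completed dataset; pooling weights across
imputations is deliberately not done.

Defaults and their rationale:

* `M = 50` imputations for full-scale runs, `M = 10` in the
  reduced-scale reproduction (between-imputation noise is inflated
  accordingly and is absorbed in the Monte-Carlo error terms).
* `n_iter = 5` burn-in cycles, the convention of the reference MICE
  implementations; with linear/logistic conditionals and
  observed-margin initialization the chains mix almost immediately. A
  drifting-chain warning fires if the imputed-variable means move
  monotonically across all cycles (checked when `n_iter >= 6`).
* `predictors = "all"`: every time-indexed variable predicts every
  incomplete one. A stricter `"matched"` mode (lagged treatment,
  confounder and outcome history only, mirroring the IPMW models) is
  available for sensitivity analyses; the default was chosen for
  congeniality with the weighted analysis model, which standard MI
  guidance favours.
* `q = 5` PMM donors, the conventional default.

## The data generator

No external data ship with the package; the generator plays the role of
a registry-like cohort with known truth. The structural equations, all
parameters of which live in `inst/extdata/dgp-defaults.yaml`, are:

* $B_{\mathrm{bin}} \sim \mathrm{Bernoulli}(0.06)$ (a rare baseline
  trait, e.g. current smoking); $B_{\mathrm{cont}} \sim 18 + 72 \cdot
  \mathrm{Beta}(5, 3)$, an age-like right-heavy distribution with mean
  63, entering all linear predictors standardized (exact analytic
  centring, so its population mean contribution is zero);
* $X_0 = 0.3 B_{\mathrm{bin}} + 0.3 b_z + \varepsilon$,
  $X_t = 0.5 X_{t-1} + \theta_x A_{t-1} + 0.3 B_{\mathrm{bin}} + 0.2 b_z +
  \varepsilon$ — treatment relieves the disease-activity-like
  confounder with a one-visit lag;
* $\mathrm{logit}\, P(A_t = 1) = -0.8 + 1.2 A_{t-1} + 0.5 X_t
  - 0.3 Y_{t-1} + 0.2 B_{\mathrm{bin}} + 0.2 b_z$ for $t \ge 1$
  (treatment persistence, confounding by current disease activity and
  previous outcome); $A_0 \equiv 0$;
* $Y_t = 0.5 + \theta_y A_t + \theta_{y,lag} A_{t-1} - 0.3 X_t
  - 0.2 B_{\mathrm{bin}} - 0.2 b_z + e_t$, with no autoregressive
  outcome term by default (`y_lag` in the config flips that switch).

The treatment-effect coefficients $(\theta_y, \theta_{y,lag}, \theta_x)$
are rescaled by a common multiplier — `calibrate_ate()`, a secant root
search on the interventional oracle — so that the always-vs-never
contrast in mean $Y_4$ equals exactly $0.2$. Because the outcome noise
is additive with mean zero and the confounder equation is linear, the
contrast is linear in the multiplier and the calibrated value is exact;
`true_ate_oracle()` verifies it by simulating both counterfactual arms
with common random numbers (the arm difference is then deterministic,
so the check is sharp even at moderate cohort sizes). Skewed-outcome
configurations flip the sign of all three effect coefficients, giving a
true ATE of $-0.2$.

**Outcome noise.** Three families: standard normal; and two right-skewed
variants built from a log-normal (sdlog 0.5 for "low" skew, 1.0 for
"high", giving theoretical skewness about 1.8 and 6.2), shifted to mean
zero and rescaled to the same standard deviation as the normal family
so the skew scenarios differ in shape only, not in noise scale. The
mean structure stays linear, so the MSM remains correctly specified for
the mean in every scenario — what changes is the validity of the
*imputation* model's normality assumption.

**Missingness.** Imposed only at visits $t \ge 1$ (baseline data are
complete, as in registries where baseline is captured at enrolment),
through logistic models whose predictors are exclusively *lagged*
quantities $(A_{t-1}, X_{t-1}, Y_{t-1}, B)$. Current-visit values never
enter, which makes the mechanism missing-at-random by construction even
when outcome and confounder are blanked simultaneously — a property the
test suite verifies directly by checking that current values do not
predict blanking given the lagged history. Five patterns:

* `nm_outcome`, `nm_confounder`: intermittent blanking of one variable;
* `nm_both`: one draw blanks both at the affected visit;
* `monotone`: drop-out only, a discrete-time hazard propagated
  absorbingly;
* `mixed`: independent intermittent draws for outcome and confounder
  plus drop-out — the registry-like mixture of all three patterns.

All non-monotone patterns also include drop-out, as in the cohorts that
motivate the design. The "low" level targets 10% of person-visits
blanked non-monotonically plus 10% censored by drop-out; "high" targets
25% and 25%, marginally over person-visits $t \ge 1$. The model
intercepts that realize these proportions are found by bisection
against a 50,000-person simulated cohort
(`calibrate_missingness_intercepts()`; drop-out first, then the
intermittent intercept with drop-out in place) and ship pre-computed in
the config for every grid cell; any other configuration is calibrated
on demand and cached. Realized proportions match targets to within one
percentage point.

**Misspecification scenarios.** The true outcome and missingness
mechanisms gain an interaction between the two confounders
($b_z \times X_t$, lagged in the missingness models), scaled so it
accounts for about 5% ("low") or 15% ("high") of the linear-predictor
variance; the analysis models — imputation models and missingness
weights alike — omit it. Because $b_z$ is exactly centred, the
interaction leaves the true ATE unchanged, so the bias these scenarios
produce is attributable to the analysis-model misspecification alone.
The two shares behave quite differently in the reproduction runs: the
low setting leaves the MI bias near 1–2% of the truth, while the high
setting produces a systematic positive MI bias of roughly 0.035–0.04
(about a fifth of the true effect) — the complete-data reference stays
unbiased in the same cells, confirming the effect comes from the
omitted term, and the MI-over-IPW rMSE advantage persists throughout.
The 15% share is, in other words, a genuinely harsh misspecification,
and results under it should be read as a stress test rather than a
mild perturbation.

## Performance measures and problem sizes

`run_scenario()` reports, per method: mean estimate, bias, empirical SE
(the SD of the estimates), and rMSE, each with a Monte-Carlo standard
error — published simulation tables rarely carry these, but at reduced
replication counts they are essential for judging whether an observed
bias is real. The identity
$\mathrm{rMSE}^2 = \mathrm{bias}^2 + \mathrm{empSE}^2 (R-1)/R$ holds by
construction and is asserted in the tests. Replication failures are
recorded with their reason, never dropped; a scenario with more than 5%
failures is flagged invalid.

The full factorial grid (`scenario_grid("full")`) is 5000 persons, 1000
replications and M = 50 per cell, plus n = 1000 twins of the
normal-outcome cells. The package's reproduction runs — the acceptance
script and the heavier tests — use the reduced twin grid
(`scenario_grid("reduced")`): n = 1000, 200 replications, M = 10, with
the Monte-Carlo widening of all tolerances that this implies. The
test-suite checks use 80–100 replications per cell under the same
widening. Every replication derives its generation, blanking and
imputation seeds from the scenario's single master seed, so any cell
reruns bit-identically from its manifest (`run_manifest()`).

## What the generator does and does not emulate

The generator reproduces the *structure* of the motivating setting —
treatment-confounder feedback, registry-like missingness patterns at
realistic rates, a rare binary and an age-like baseline covariate, a
skewed outcome option — with known truth. It does not attempt to match
any real registry's empirical distributions, visit spacing, or
measurement properties: visits are equally spaced and fully attended
apart from the imposed missingness, missingness is exactly MAR,
treatment is binary with no dose or switching costs, and there is no
effect modification or long-range direct effect ($A_t$ affects later
outcomes only through the confounder chain). Passing results therefore
demonstrate that the estimators behave as the theory predicts *under
these conditions*; they do not certify performance under MNAR
mechanisms, informative visit timing, or effect heterogeneity, all of
which are out of scope here.

## Numerical notes

* Logistic weight models are fitted by `glm.fit` on hand-built design
  matrices; within an imputation stack successive fits warm-start from
  the previous completed dataset's coefficients.
* Imputation-model draws use a Cholesky factorization of $X'X$ with a
  QR fallback that drops collinear columns (with a warning) rather than
  aborting.
* Perfect separation aborts a weight-model fit with a diagnostic; in
  the logistic *imputer* it instead falls back to a ridge-penalized fit
  (the imputation must produce values), logged via a warning.
* PMM donor search sorts the observed predictions once and scans a
  clamped window of $2q$ candidates per missing case, de-duplicating
  boundary clamps so no donor counts twice toward the $q$ nearest; ties
  at the $q$-th distance are all included before the uniform donor
  draw.
* Degenerate requests are handled explicitly: a zero missingness target
  returns an infinite negative intercept ("never missing"); a panel
  with no missing cells short-circuits `mice_run()` to M identical
  copies; degenerate missingness models produce unit weights.

## A minimal session

```{r}
library(mimsm)

co <- dgp_coefficients()        # calibrated defaults, true ATE = 0.2
sp <- scenario_spec("nm_both", "high", n = 1000, n_reps = 50, M = 10,
                    base_seed = 7)

panel <- generate_complete_panel(sp, co, seed = 1)
obs   <- impose_missingness(panel, sp, co, seed = 2)

ate_ipw(obs)                    # censor-and-reweight
ate_mi(obs, M = 10, seed = 3)   # impute-then-weight

res <- run_scenario(sp, methods = c("IPW", "MI_linear"))
res$performance
```
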