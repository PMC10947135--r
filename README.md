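# mimsm

Estimating the effect of a *time-varying* treatment from longitudinal
observational data runs into two problems at once: time-varying
confounding (the evolving disease state drives both the next treatment
decision and the outcome, and is itself affected by earlier treatment)
and missing data (outcomes and time-varying covariates collected by
follow-up questionnaire go missing — some patients drop out for good,
others skip visits or items intermittently). `mimsm` is a simulation
and estimation toolkit for comparing the two standard answers to the
missing-data half of that problem while the confounding half is handled
by inverse-probability-of-treatment-weighted marginal structural models
(MSMs):

* **IPW approach** — censor each person at their first missing
  observation, model the discrete-time hazard of remaining observed,
  and multiply stabilized inverse-probability-of-missingness weights
  into the stabilized treatment weights;
* **MI approach** — multiple imputation by chained equations (Bayesian
  linear regression, logistic regression, or predictive mean matching
  per variable), the weighted MSM refitted in every completed dataset
  and pooled by Rubin's rules, V = W + (1 + 1/M)B.

## The model

For visits t = 0..4 with binary treatment A_t (A_0 = 0), time-varying
confounder X_t, outcome Y_t and baseline covariates B, the MSM is

    E[Y_4^ā | B] = α + Σ_t β_t a_t + γ'B,

fitted by weighted least squares with cumulative stabilized weights

    SW = Π_t P(A_t | A_{t-1}, B) / P(A_t | A_{t-1}, X_t, Y_{t-1}, B),

and the estimand is the always-treat vs never-treat contrast
ATE = Σ_t β_t at the end of follow-up. The package ships a calibrated
longitudinal data generator (5 visits, treatment-confounder feedback,
monotone and non-monotone missing-at-random missingness at 10% or 25%
levels, optional right-skewed outcome and analysis-model
misspecification) whose interventional true ATE is exactly 0.2 (−0.2
in the skewed variants), plus a factorial simulation harness measuring
bias, empirical SE and rMSE per method. See the vignette
(`vignettes/mimsm-methods.Rmd`) for the full model, the generator's
equations, and every tunable parameter.

## Worked example

Generate one registry-like cohort, blank cells under the heavy
non-monotone pattern (25% intermittent + 25% drop-out person-visits),
and estimate the ATE both ways:

```r
library(mimsm)

co <- dgp_coefficients()      # shipped calibrated defaults, true ATE 0.2
sp <- scenario_spec("nm_both", "high", n = 1000, n_reps = 50, M = 10,
                    base_seed = 7)

panel <- generate_complete_panel(sp, co, seed = 1)
obs   <- impose_missingness(panel, sp, co, seed = 2)

ate_ipw(obs)
#>    estimate          se      n_used
#>  -0.5233489   0.4647407 149.0000000
ate_mi(obs, M = 10, seed = 3)
#>      estimate            se        n_used
#>   -0.09172564    0.23521447 1000.00000000
```

On this single dataset the weighting approach keeps only the 149
persons observed at every visit and its estimate swings accordingly
(here to −0.52, with a standard error to match), while imputation
retains all 1000 persons. Replicating 50 times shows that both methods
centre on the truth but weighting is far less precise:

```r
res <- run_scenario(sp, methods = c("IPW", "MI_linear"))
res$performance[, c("method", "n_reps", "mean_estimate", "bias", "emp_se", "rmse")]
#>      method n_reps mean_estimate          bias    emp_se      rmse
#> 1       IPW     50     0.1099292 -0.0900708208 0.4323188 0.4373492
#> 2 MI_linear     50     0.1996720 -0.0003279889 0.1915939 0.1896686
```

Each method's bias is within Monte-Carlo error of zero (the MC-SE of
the IPW bias at 50 replications is 0.43/√50 ≈ 0.06), and the rMSE of
the weighting approach is more than twice that of imputation — the
pattern that holds across the whole scenario grid (`scenario_grid()`).

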