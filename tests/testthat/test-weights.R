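test_that("treatment models recover the generating coefficients at large n", {
  p <- generate_complete_panel(scenario_spec("monotone", "low", n = 1e5), CO, seed = 51)
  tm <- fit_treatment_models(p)
  ## independent oracle fit with model-based SEs
  lf <- mimsm:::lagged_frame(p)
  lf$bz <- (lf$b_cont - mean(p$b_cont)) / sd(p$b_cont)
  or <- glm(a ~ a_lag + x + y_lag + b_bin + bz + factor(t),
            family = binomial(), data = lf)
  se <- summary(or)$coefficients[, "Std. Error"]
  truth <- c(CO$a$intercept, CO$a$lag, CO$a$x, CO$a$y_lag, CO$a$b_bin,
             CO$a$b_cont * CO$b_cont$scale / sd(p$b_cont), 0, 0, 0)
  expect_true(all(abs(coef(or) - truth) < 3.5 * se))
  ## package fit agrees with the oracle route
  expect_equal(unname(tm$den), unname(coef(or)), tolerance = 1e-6)
})

test_that("stabilized weight ratios follow the definition and accumulate multiplicatively", {
  p <- make_fixture("complete")
  p$a[p$t >= 1] <- 1L   # everyone treated: realized prob = model prob
  tm <- stub_treatment_models(p_den = 0.25, p_num = 0.5)
  sw <- stabilized_treatment_weights(p, tm)
  one <- sw[sw$id == 1, ]
  expect_equal(one$ratio, c(1, 2, 2, 2, 2))          # 0.5 / 0.25
  expect_equal(one$cum_weight, c(1, 2, 4, 8, 16))    # cumulative product
  ## cumulative invariant across the whole vector
  expect_equal(sw$cum_weight[sw$t == 3], sw$cum_weight[sw$t == 2] * sw$ratio[sw$t == 3])
})

test_that("stabilized weights average one per visit and balance confounders", {
  p <- generate_complete_panel(scenario_spec("monotone", "low", n = 1e5), CO, seed = 52)
  tm <- fit_treatment_models(p)
  sw <- stabilized_treatment_weights(p, tm)
  for (tt in 1:4) {
    w <- sw$cum_weight[sw$t == tt]
    expect_lt(abs(mean(w) - 1), 3 * sd(w) / sqrt(length(w)))
  }
  ## in the pseudo-population reweighted by the visit-level inverse
  ## denominator probability, treatment is assigned independently of the
  ## confounder: standardized mean difference of X between arms < 0.05.
  ## (Stabilized cumulative weights balance conditionally on the
  ## numerator covariates, not marginally, so the sharp marginal check
  ## uses the unstabilized visit weight.)
  for (tt in 1:4) {
    w <- 1 / sw$p_den[sw$t == tt]
    a <- p$a[p$t == tt]; x <- p$x[p$t == tt]
    m1 <- weighted.mean(x[a == 1], w[a == 1]); m0 <- weighted.mean(x[a == 0], w[a == 0])
    smd <- abs(m1 - m0) / sd(x)
    expect_lt(smd, 0.05)
  }
})

test_that("no-confounding generating process gives weights collapsing to one", {
  p <- generate_complete_panel(scenario_spec("monotone", "low", n = 50000),
                               co_unconfounded(), seed = 53)
  tm <- fit_treatment_models(p)
  sw <- stabilized_treatment_weights(p, tm)
  w4 <- sw$cum_weight[sw$t == 4]
  expect_lt(var(w4), 0.005)
  expect_lt(abs(mean(w4) - 1), 0.01)
})

test_that("censoring at first missing observation monotonizes every pattern", {
  ## intermittent single-variable missing from t = 1: all later visits censored
  p1 <- censor_after_first_missing(make_fixture("table1_patient1"))
  one <- p1[p1$id == 1, ]
  expect_equal(one$r_x, c(1L, 0L, 0L, 0L, 0L))
  expect_equal(one$r_y, c(1L, 0L, 0L, 0L, 0L))
  ## fully complete id unchanged
  comp <- make_fixture("complete")
  expect_identical(censor_after_first_missing(comp), comp)
  ## already-monotone drop-out unchanged
  p3 <- make_fixture("dropout")
  expect_identical(censor_after_first_missing(p3), p3)
  ## result is monotone for every id in the mixed fixture
  pm <- censor_after_first_missing(make_fixture("mixed"))
  obs <- tapply(pm$r_x * pm$r_y, pm$id, function(r) all(diff(r) <= 0))
  expect_true(all(unlist(obs)))
})

test_that("missingness hazard models recover the drop-out mechanism", {
  ## monotone-only scenario: logit P(observed) = -logit P(drop-out)
  sp <- scenario_spec("monotone", "high", n = 1e5)
  p <- generate_complete_panel(sp, CO, seed = 54)
  pm <- impose_missingness(p, sp, CO, seed = 55)
  cen <- censor_after_first_missing(pm)
  mm <- fit_missingness_models(cen)
  sl <- CO$miss$slopes$dropout
  ## logit P(observed) = -logit P(drop-out): slopes negate
  truth <- -c(sl$a_lag, sl$y_lag, sl$x_lag, sl$b_bin,
              sl$b_cont * CO$b_cont$scale / sd(p$b_cont))
  ## oracle fit for model-based SEs on the same risk sets
  lf <- mimsm:::lagged_frame(cen)
  lf$bz <- (lf$b_cont - mean(cen$b_cont)) / sd(cen$b_cont)
  atrisk <- !is.na(lf$x_lag) & !is.na(lf$y_lag)
  lf$r <- as.integer(lf$r_x == 1 & lf$r_y == 1)
  or <- glm(r ~ a_lag + y_lag + x_lag + b_bin + bz + factor(t),
            family = binomial(), data = lf[atrisk, ])
  se <- summary(or)$coefficients[2:6, "Std. Error"]
  est <- mm$den[2:6]
  expect_true(all(abs(est - truth) < 3.5 * se))
  expect_equal(unname(est), unname(coef(or)[2:6]), tolerance = 1e-6)
  ## intercept recovers the negated calibrated drop-out intercept
  shipped <- CO$miss$intercepts[["monotone_high_normal_none"]]$dropout
  expect_lt(abs(mm$den[1] + shipped), 0.1)
})

test_that("missingness models refuse non-monotone input and degenerate to one without missingness", {
  expect_error(fit_missingness_models(make_fixture("table1_patient1")), "non-monotone")
  comp <- make_fixture("complete")
  mm <- fit_missingness_models(comp)
  expect_true(mm$degenerate)
  mw <- stabilized_missingness_weights(comp, mm)
  expect_true(all(mw$cum_weight == 1))
})

test_that("total weights multiply componentwise and require a common support", {
  p <- make_fixture("complete")
  sw <- stabilized_treatment_weights(p, stub_treatment_models(0.25, 0.5))
  mw <- stabilized_missingness_weights(p, fit_missingness_models(p))  # all ones
  tw <- total_weights(sw, mw)
  expect_equal(tw$cum_weight, sw$cum_weight)  # mw = 1 identity
  ## arithmetic: SW = 1.5, mw_Y = 2.0, mw_X = 1.2 -> 3.6
  mk <- function(cum) mimsm:::new_weight_vector(1L, 0L, NA, NA, cum, cum, "k")
  expect_equal(total_weights(mk(1.5), mk(2.0), mk(1.2))$cum_weight, 3.6)
  bad <- mw[mw$id != 1, ]
  expect_error(total_weights(sw, bad), "support")
})

test_that("total weights are more variable than treatment weights under heavy missingness", {
  sp <- scenario_spec("nm_both", "high", n = 20000)
  p <- generate_complete_panel(sp, CO, seed = 56)
  pm <- impose_missingness(p, sp, CO, seed = 57)
  cen <- censor_after_first_missing(pm)
  tm <- fit_treatment_models(cen)
  sw <- stabilized_treatment_weights(cen, tm, na_action = "na")
  mw <- stabilized_missingness_weights(cen, fit_missingness_models(cen))
  tw <- total_weights(sw, mw)
  ok <- !is.na(tw$cum_weight) & tw$t == 4
  expect_gt(var(tw$cum_weight[ok]), var(sw$cum_weight[ok]))
})
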