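test_that("complete panel has the sequential structure and marginals", {
  sp <- scenario_spec("nm_both", "high", n = 5000)
  p <- generate_complete_panel(sp, CO, seed = 1)
  expect_equal(nrow(p), 25000)
  expect_false(anyNA(p$x)); expect_false(anyNA(p$y))
  expect_true(all(p$r_x == 1 & p$r_y == 1 & p$c == 0))
  expect_true(all(p$a[p$t == 0] == 0))
  ## binary baseline prevalence 6% within 3 binomial MC-SEs
  f <- mean(p$b_bin[p$t == 0])
  expect_lt(abs(f - 0.06), 3 * sqrt(0.06 * 0.94 / 5000))
  ## continuous baseline inside its configured range, age-like mean
  b <- p$b_cont[p$t == 0]
  expect_true(all(b >= 18 & b <= 90))
  expect_lt(abs(mean(b) - 63), 1)
  ## positivity at every post-baseline visit
  pa <- tapply(p$a, p$t, mean)[-1]
  expect_true(all(pa > 0.05 & pa < 0.95))
})

test_that("zero treatment-model slopes give a constant treatment probability", {
  co <- co_unconfounded()
  co$a$intercept <- -0.5
  p <- generate_complete_panel(scenario_spec("monotone", "low", n = 20000), co, seed = 7)
  target <- 1 / (1 + exp(0.5))
  pa <- tapply(p$a, p$t, mean)[-1]
  mc <- 3 * sqrt(target * (1 - target) / 20000)
  expect_true(all(abs(pa - target) < mc))
})

test_that("interventional ATE oracle: null effect is exactly zero, shipped sets hit their targets", {
  ## common random numbers make the arm difference deterministic given
  ## additive noise, so tolerances can be tight at moderate n
  expect_equal(true_ate_oracle(co_null_effect(), n_large = 5000, seed = 3), 0)
  expect_lt(abs(true_ate_oracle(CO, n_large = 50000, seed = 3) - 0.2), 0.002)
  co_sk <- dgp_coefficients("skew_high")
  expect_lt(abs(true_ate_oracle(co_sk, n_large = 50000, seed = 3) - (-0.2)), 0.002)
  co_ms <- dgp_coefficients("normal", "high")
  expect_lt(abs(true_ate_oracle(co_ms, n_large = 200000, seed = 3) - 0.2), 0.005)
})

test_that("calibrate_ate rescales effects to an arbitrary target", {
  co <- calibrate_ate(CO, target = 0.35, n_large = 50000, seed = 5)
  expect_lt(abs(true_ate_oracle(co, 50000, seed = 9) - 0.35), 0.002)
  co0 <- calibrate_ate(CO, target = 0)
  expect_equal(co0$y$a, 0)
  expect_equal(co0$x$a_lag, 0)
  expect_error(calibrate_ate(co_null_effect(), target = 0.2), "sign-compatible")
})

test_that("imposed missingness hits the scenario proportions within 1 pp", {
  for (args in list(c("nm_both", "high"), c("mixed", "low"), c("nm_outcome", "high"))) {
    sp <- scenario_spec(args[1], args[2], n = 20000)
    p <- generate_complete_panel(sp, CO, seed = 11)
    pm <- impose_missingness(p, sp, CO, seed = 12)
    idx <- pm$t >= 1
    nonmono <- mean((pm$r_x[idx] == 0 | pm$r_y[idx] == 0) & pm$c[idx] == 0)
    mono <- mean(pm$c[idx] == 1)
    expect_lt(abs(nonmono - sp$nonmono_target), 0.01)
    expect_lt(abs(mono - sp$mono_target), 0.01)
    ## baseline never blanked, treatment always recorded
    expect_false(anyNA(pm$x[pm$t == 0])); expect_false(anyNA(pm$y[pm$t == 0]))
    expect_false(anyNA(pm$a))
  }
})

test_that("monotone pattern produces only absorbing drop-out missingness", {
  sp <- scenario_spec("monotone", "low", n = 5000)
  p <- generate_complete_panel(sp, CO, seed = 21)
  pm <- impose_missingness(p, sp, CO, seed = 22)
  expect_silent(validate_panel(pm))
  ## every missing cell is a drop-out cell
  expect_true(all(pm$c[pm$r_x == 0] == 1))
  expect_true(all(pm$c[pm$r_y == 0] == 1))
  ## per-id missingness is a suffix
  m <- split(pm$r_y, pm$id)
  expect_true(all(vapply(m, function(r) all(diff(r) <= 0), logical(1))))
})

test_that("missingness is MAR by construction: current values do not predict blanking given history", {
  sp <- scenario_spec("nm_outcome", "high", n = 50000)
  p <- generate_complete_panel(sp, CO, seed = 31)
  pm <- impose_missingness(p, sp, CO, seed = 32)
  ## person-visits t>=1 not censored: regress the blanking indicator on
  ## the (pre-blanking) current outcome given the lagged history
  d <- data.frame(miss = (pm$r_y == 0 & pm$c == 0)[pm$t >= 1])
  cur <- p[p$t >= 1, ]; lag <- p[p$t <= 3, ]
  d$y_cur <- cur$y; d$x_cur <- cur$x
  d$a_lag <- lag$a; d$x_lag <- lag$x; d$y_lag <- lag$y
  d$b_bin <- cur$b_bin; d$b_cont <- cur$b_cont; d$t <- factor(cur$t)
  d <- d[(pm$c == 0)[pm$t >= 1], ]
  fit <- suppressWarnings(glm(miss ~ y_cur + x_cur + a_lag + x_lag + y_lag +
                                b_bin + b_cont + t, family = binomial(), data = d))
  z <- summary(fit)$coefficients[c("y_cur", "x_cur"), "z value"]
  expect_true(all(abs(z) < 3.5))
})

test_that("calibration of missingness intercepts has the closed-form MCAR limit", {
  ## with all slopes zero and no drop-out, a marginal blanking target p
  ## needs intercept logit(p)
  co <- CO
  for (nm in names(co$miss$slopes$nonmonotone)) co$miss$slopes$nonmonotone[[nm]] <- 0
  for (nm in names(co$miss$slopes$dropout)) co$miss$slopes$dropout[[nm]] <- 0
  co$miss$intercepts <- list()
  sp <- scenario_spec("nm_both", "high", n = 2000)
  sp$mono_target <- 0  # isolate the non-monotone intercept
  ic <- calibrate_missingness_intercepts(sp, co, n = 50000)
  expect_equal(ic$dropout, -Inf)
  expect_lt(abs(ic$nonmono - log(0.25 / 0.75)), 0.1)
})

test_that("skewed outcome noise is right-skewed at the configured severities and mean-zero", {
  co_lo <- dgp_coefficients("skew_low")
  co_hi <- dgp_coefficients("skew_high")
  set.seed(77)
  e_lo <- mimsm:::outcome_noise(1e5, co_lo)
  e_hi <- mimsm:::outcome_noise(1e5, co_hi)
  expect_gt(mimsm:::skewness(e_lo), 0.5)
  expect_gt(mimsm:::skewness(e_hi), 1.5)
  expect_lt(abs(mean(e_lo)), 0.02)
  expect_lt(abs(mean(e_hi)), 0.02)
  ## rescaled to the same noise scale as the normal family
  expect_lt(abs(sd(e_hi) - co_hi$y$sd), 0.05)
})
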