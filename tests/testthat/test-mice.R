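test_that("posterior parameter draws have the right first moments", {
  set.seed(101)
  n <- 60; k <- 3
  X <- cbind(1, matrix(rnorm(n * (k - 1)), n))
  y <- drop(X %*% c(1, 2, -1)) + rnorm(n, 0, 1.5)
  one <- draw_posterior_params(y, X, seed = 1)
  ## E[sigma2*] = sigma2_hat (n-k) / (n-k-2), the scaled-inverse-chi-square mean
  draws <- replicate(4000, draw_posterior_params(y, X))
  s2 <- unlist(draws["sigma2_star", ])
  target <- one$sigma2_hat * (n - k) / (n - k - 2)
  expect_lt(abs(mean(s2) - target) / target, 0.05)
  ## beta* symmetric around beta_hat
  b <- sapply(draws["beta_star", ], identity)
  expect_lt(max(abs(rowMeans(b) - one$beta_hat)), 0.05)
})

test_that("noiseless data give degenerate draws and deterministic imputations", {
  X <- cbind(1, 1:20)
  y <- drop(X %*% c(0.5, 2))
  d <- draw_posterior_params(y, X, seed = 3)
  expect_equal(d$sigma2_star, 0)
  expect_equal(d$beta_star, d$beta_hat)
  expect_equal(impute_linear(d, cbind(1, 30)), 0.5 + 2 * 30)
})

test_that("linear imputation arithmetic and distributional correctness", {
  ## beta* = (1, 2), x = (1, 3), sigma2* = 0 -> 7
  d <- structure(list(beta_star = c(1, 2), sigma2_star = 0), class = "imputation_model_draw")
  expect_equal(impute_linear(d, matrix(c(1, 3), 1)), 7)
  ## under a correctly specified normal model, imputed values are
  ## distributed like the values they replace (two-sample KS)
  set.seed(202)
  n <- 4000
  x <- rnorm(n)
  y <- 1 + 2 * x + rnorm(n)
  miss <- runif(n) < 0.3
  dr <- draw_posterior_params(y[!miss], cbind(1, x[!miss]))
  imp <- impute_linear(dr, cbind(1, x[miss]))
  ks <- suppressWarnings(ks.test(imp, y[miss]))
  expect_gt(ks$p.value, 0.01)
})

test_that("logistic imputation preserves a rare-event prevalence under MCAR", {
  set.seed(303)
  n <- 20000
  y <- rbinom(n, 1, 0.06)   # rare binary baseline covariate
  miss <- runif(n) < 0.3
  imp <- impute_logistic(y[!miss], matrix(1, sum(!miss)), matrix(1, sum(miss)))
  expect_true(all(imp %in% c(0L, 1L)))
  expect_lt(abs(mean(imp) - 0.06), 3 * sqrt(0.06 * 0.94 / sum(miss)))
})

test_that("predictive mean matching donates observed values only, nearest-first", {
  ## noiseless fit makes beta* deterministic, so q = 1 is the literal
  ## nearest neighbor in predicted mean
  x_obs <- c(1, 2, 3, 4)
  y_obs <- 2 * x_obs
  dr <- draw_posterior_params(y_obs, cbind(1, x_obs), seed = 5)
  imp <- impute_pmm(dr, cbind(1, x_obs), y_obs, cbind(1, c(1.2, 3.9)), q = 1, seed = 6)
  expect_equal(imp, c(2, 8))
  ## closure: imputations are always a subset of the observed support
  set.seed(404)
  x <- rnorm(500); y <- x + rlnorm(500)
  miss <- runif(500) < 0.4
  dr <- draw_posterior_params(y[!miss], cbind(1, x[!miss]))
  imp <- impute_pmm(dr, cbind(1, x[!miss]), y[!miss], cbind(1, x[miss]), q = 5)
  expect_true(all(imp %in% y[!miss]))
})

test_that("PMM preserves the shape of a skewed distribution better than linear imputation", {
  set.seed(505)
  n <- 6000
  x <- rnorm(n)
  y <- 1 + 0.5 * x + (rlnorm(n, 0, 1) - exp(0.5))  # right-skewed errors
  miss <- runif(n) < 0.35
  dr <- draw_posterior_params(y[!miss], cbind(1, x[!miss]))
  imp_pmm <- impute_pmm(dr, cbind(1, x[!miss]), y[!miss], cbind(1, x[miss]), q = 5)
  imp_lin <- impute_linear(dr, cbind(1, x[miss]))
  ## sample skewness of heavy-tailed data is itself noisy, so the check
  ## is qualitative: matched donors keep the right-skew, normal draws
  ## erase it entirely
  sk_obs <- mimsm:::skewness(y[!miss])
  expect_gt(mimsm:::skewness(imp_pmm), 2)
  expect_lt(abs(mimsm:::skewness(imp_lin)), 0.5)
  expect_lt(abs(mimsm:::skewness(imp_pmm) - sk_obs),
            abs(mimsm:::skewness(imp_lin) - sk_obs))
})

test_that("chained equations return reproducible stacks that honour observed cells", {
  sp <- scenario_spec("mixed", "high", n = 400)
  p <- generate_complete_panel(sp, CO, seed = 61)
  pm <- impose_missingness(p, sp, CO, seed = 62)
  s1 <- mice_run(pm, M = 3, n_iter = 3, seed = 99)
  s2 <- mice_run(pm, M = 3, n_iter = 3, seed = 99)
  expect_identical(s1$panels, s2$panels)            # bit-identical rerun
  for (cp in s1$panels) {
    expect_false(anyNA(cp$x)); expect_false(anyNA(cp$y))
    obs <- pm$r_y == 1
    expect_identical(cp$y[obs], pm$y[obs])          # observed cells untouched
    expect_identical(cp$x[pm$r_x == 1], pm$x[pm$r_x == 1])
  }
  ## different seeds differ in the imputed cells
  s3 <- mice_run(pm, M = 3, n_iter = 3, seed = 100)
  expect_false(identical(s1$panels[[1]]$y, s3$panels[[1]]$y))
})

test_that("a complete panel yields M identical copies of itself", {
  p <- make_fixture("complete")
  st <- mice_run(p, M = 4, seed = 1)
  expect_length(st$panels, 4)
  for (cp in st$panels) expect_identical(cp$y, p[order(p$id, p$t), ]$y)
})

test_that("Rubin's rules pool with the stated arithmetic and variance identity", {
  pe <- rubin_combine(c(1, 2, 3), c(0.1, 0.1, 0.1))
  expect_equal(pe$theta, 2)
  expect_equal(pe$W, 0.1)
  expect_equal(pe$B, 1)
  expect_equal(pe$V, 0.1 + (1 + 1 / 3) * 1)
  ## identical estimates: no between-imputation variance
  pe0 <- rubin_combine(rep(1.5, 5), rep(0.2, 5))
  expect_equal(pe0$B, 0); expect_equal(pe0$V, pe0$W)
  ## V = W + (1 + 1/M) B exactly, and V >= W, on random inputs
  set.seed(606)
  for (i in 1:20) {
    th <- rnorm(7); v <- rchisq(7, 3)
    pe <- rubin_combine(th, v)
    expect_identical(pe$V, pe$W + (1 + 1 / 7) * pe$B)
    expect_gte(pe$V, pe$W)
  }
  expect_error(rubin_combine(1, 0.1), "M >= 2")
})

test_that("proper imputation gives nominal interval coverage under MCAR", {
  ## correctly specified univariate setting: impute y | x, estimate E[Y]
  set.seed(707)
  n <- 250; M <- 10; reps <- 500
  cover <- logical(reps)
  for (r in seq_len(reps)) {
    x <- rnorm(n)
    y <- x + rnorm(n)          # E[Y] = 0
    miss <- runif(n) < 0.4
    th <- vs <- numeric(M)
    for (m in seq_len(M)) {
      dr <- draw_posterior_params(y[!miss], cbind(1, x[!miss]))
      yc <- y; yc[miss] <- impute_linear(dr, cbind(1, x[miss]))
      th[m] <- mean(yc)
      vs[m] <- var(yc) / n
    }
    ci <- confint(rubin_combine(th, vs))
    cover[r] <- ci[1] <= 0 && 0 <= ci[2]
  }
  expect_gte(mean(cover), 0.92)
  expect_lte(mean(cover), 0.98)
})
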