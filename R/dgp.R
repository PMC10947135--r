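## Data-generating process: sequential longitudinal structure
##   B -> X_0 -> Y_0, then for t >= 1: X_t | A_{t-1}, X_{t-1}, B;
##   A_t ~ Bernoulli(expit(lp(A_{t-1}, X_t, Y_{t-1}, B)));
##   Y_t | A_t, A_{t-1}, X_t, B (+ optional Y_{t-1} term, off by default).
## Within a visit the ordering is X_t -> A_t -> Y_t, so the outcome
## available at the treatment decision is the previous visit's.

## simulate per-person matrices; regime = NULL draws treatment from its
## logistic model, regime = 0/1 forces A_t for all t >= 1 (counterfactual
## arms). Identical seeds give identical noise across regimes because
## forced arms skip the treatment draws in the same places.
gen_mats <- function(n, coeffs, seed, regime = NULL) {
  set.seed(seed)
  co <- coeffs
  T_ <- co$n_visits
  b_bin <- stats::rbinom(n, 1L, co$b_bin_prevalence)
  b_cont <- co$b_cont$min +
    (co$b_cont$max - co$b_cont$min) * stats::rbeta(n, co$b_cont$shape1, co$b_cont$shape2)
  bz <- (b_cont - co$b_cont$center) / co$b_cont$scale

  X <- A <- Y <- matrix(0, n, T_)
  X[, 1] <- co$x0$intercept + co$x0$b_bin * b_bin + co$x0$b_cont * bz +
    stats::rnorm(n, 0, co$x0$sd)
  A[, 1] <- 0
  Y[, 1] <- co$y$intercept + co$y$x * X[, 1] + co$y$b_bin * b_bin +
    co$y$b_cont * bz + co$y$x_bcont * bz * X[, 1] + outcome_noise(n, co)
  for (t in 2:T_) {
    X[, t] <- co$x$intercept + co$x$lag * X[, t - 1] + co$x$a_lag * A[, t - 1] +
      co$x$b_bin * b_bin + co$x$b_cont * bz + stats::rnorm(n, 0, co$x$sd)
    if (is.null(regime)) {
      lp <- co$a$intercept + co$a$lag * A[, t - 1] + co$a$x * X[, t] +
        co$a$y_lag * Y[, t - 1] + co$a$b_bin * b_bin + co$a$b_cont * bz
      if (any(!is.finite(lp)))
        stop("non-finite treatment linear predictor at visit ", t - 1,
             "; check the 'a' coefficient block")
      A[, t] <- stats::rbinom(n, 1L, expit(lp))
    } else {
      A[, t] <- regime
    }
    Y[, t] <- co$y$intercept + co$y$a * A[, t] + co$y$a_lag * A[, t - 1] +
      co$y$x * X[, t] + co$y$y_lag * Y[, t - 1] + co$y$b_bin * b_bin +
      co$y$b_cont * bz + co$y$x_bcont * bz * X[, t] + outcome_noise(n, co)
    if (any(!is.finite(Y[, t])))
      stop("non-finite outcome at visit ", t - 1, "; check the 'y' coefficient block")
  }
  list(ids = seq_len(n), n = n, T = T_, b_bin = b_bin, b_cont = b_cont, bz = bz,
       X = X, A = A, Y = Y,
       RX = matrix(1L, n, T_), RY = matrix(1L, n, T_), C = matrix(0L, n, T_))
}

#' Generate a complete longitudinal panel
#'
#' Simulates `spec$n` persons over 5 visits from the sequential
#' structural model (time-constant confounders, a treatment-affected
#' time-varying confounder, a logistic treatment-assignment process and a
#' linear outcome equation). All observation indicators are 1. Treatment
#' at the initial visit is structurally zero.
#'
#' Positivity is checked empirically: for panels with at least 500
#' persons the realized treatment frequency must lie strictly inside
#' (0.05, 0.95) at every visit after baseline.
#'
#' @param spec a [scenario_spec()]
#' @param coeffs a [dgp_coefficients()] object
#' @param seed RNG seed
#' @return a complete panel (see [validate_panel()])
#' @export
generate_complete_panel <- function(spec, coeffs, seed) {
  m <- gen_mats(spec$n, coeffs, seed)
  if (spec$n >= 500) {
    pa <- colMeans(m$A[, -1, drop = FALSE])
    if (any(pa <= 0.05 | pa >= 0.95))
      stop("positivity violated: empirical P(A_t = 1) = ",
           paste(signif(pa, 3), collapse = ", "),
           " not strictly inside (0.05, 0.95)")
  }
  mats_panel(m)
}

#' Interventional true ATE of a coefficient set
#'
#' Simulates two counterfactual cohorts with treatment forced to 1
#' ("always treat") respectively 0 ("never treat") at every visit after
#' baseline, using common random numbers, and returns the difference in
#' mean outcome at the final visit. This is the estimand the estimation
#' pipelines target, and the quantity [calibrate_ate()] pins to the
#' configured value.
#'
#' @param coeffs a [dgp_coefficients()] object
#' @param n_large cohort size per arm (>= 1e6 recommended for
#'   calibration-grade precision)
#' @param seed RNG seed (shared across arms)
#' @return scalar mean difference, in outcome units
#' @export
true_ate_oracle <- function(coeffs, n_large = 1e6, seed = 1) {
  T_ <- coeffs$n_visits
  m1 <- gen_mats(n_large, coeffs, seed, regime = 1L)
  m0 <- gen_mats(n_large, coeffs, seed, regime = 0L)
  mean(m1$Y[, T_]) - mean(m0$Y[, T_])
}

#' Calibrate treatment-effect coefficients to a target ATE
#'
#' Rescales the direct (`y$a`, `y$a_lag`) and mediated (`x$a_lag`)
#' treatment-effect coefficients by a common multiplier, found by secant
#' root search on [true_ate_oracle()], until the interventional ATE is
#' within `tol` of `target`. With additive zero-mean outcome noise the
#' ATE is exactly linear in the multiplier, so the search converges in
#' one step up to Monte-Carlo error.
#'
#' @inheritParams true_ate_oracle
#' @param target desired true ATE (finite)
#' @param tol calibration tolerance
#' @param max_iter maximum secant refinements
#' @return a `dgp_coefficients` object with rescaled effects
#' @export
calibrate_ate <- function(coeffs, target, n_large = 1e6, seed = 1,
                          tol = 0.002, max_iter = 6) {
  stopifnot(is.finite(target))
  scale_by <- function(co, mult) {
    co$y$a <- co$y$a * mult
    co$y$a_lag <- co$y$a_lag * mult
    co$x$a_lag <- co$x$a_lag * mult
    co
  }
  if (target == 0) {
    out <- scale_by(coeffs, 0)
    out$true_ate <- 0
    return(out)
  }
  a1 <- true_ate_oracle(coeffs, n_large, seed)
  if (a1 == 0)
    stop("no sign-compatible multiplier: coefficient set has zero treatment effect")
  mult <- target / a1
  out <- scale_by(coeffs, mult)
  for (i in seq_len(max_iter)) {
    ate <- true_ate_oracle(out, n_large, seed)
    if (abs(ate - target) <= tol) break
    step <- target / ate
    if (!is.finite(step)) stop("no sign-compatible multiplier found")
    out <- scale_by(out, step)
  }
  out$true_ate <- target
  out
}

## ---------------------------------------------------------------------
## Missingness imposition
## ---------------------------------------------------------------------

## All missingness models are logistic in *lagged* quantities only
## (A_{t-1}, X_{t-1}, Y_{t-1}, B, plus the bz*X_{t-1} interaction under
## misspecification): current-visit values never enter, which makes the
## mechanism missing-at-random by construction even when outcome and
## confounder are blanked simultaneously.
miss_lp <- function(slopes, x_bcont, A_lag, X_lag, Y_lag, b_bin, bz) {
  slopes$a_lag * A_lag + slopes$x_lag * X_lag + slopes$y_lag * Y_lag +
    slopes$b_bin * b_bin + slopes$b_cont * bz + x_bcont * bz * X_lag
}

## core blanking engine on matrices; uniforms are pre-drawn so the
## realized proportions are monotone in the intercepts (used by the
## calibration bisection)
apply_missingness <- function(m, spec, coeffs, icpt, u_drop, u_y, u_x) {
  T_ <- m$T
  sl <- coeffs$miss$slopes
  xb <- coeffs$miss$x_bcont
  C <- matrix(0L, m$n, T_)
  dropped <- rep(FALSE, m$n)
  for (t in 2:T_) {
    if (is.finite(icpt$dropout)) {
      p <- expit(icpt$dropout +
                   miss_lp(sl$dropout, xb, m$A[, t - 1], m$X[, t - 1],
                           m$Y[, t - 1], m$b_bin, m$bz))
      dropped <- dropped | (!dropped & u_drop[, t - 1] < p)
    }
    C[dropped, t] <- 1L
  }
  missY <- missX <- matrix(FALSE, m$n, T_)
  if (spec$pattern != "monotone" && is.finite(icpt$nonmono)) {
    for (t in 2:T_) {
      lp <- icpt$nonmono +
        miss_lp(sl$nonmonotone, xb, m$A[, t - 1], m$X[, t - 1],
                m$Y[, t - 1], m$b_bin, m$bz)
      p <- expit(lp)
      alive <- C[, t] == 0L
      switch(spec$pattern,
        nm_outcome = { missY[, t] <- alive & (u_y[, t - 1] < p) },
        nm_confounder = { missX[, t] <- alive & (u_x[, t - 1] < p) },
        nm_both = {
          hit <- alive & (u_y[, t - 1] < p)
          missY[, t] <- hit; missX[, t] <- hit
        },
        mixed = {
          missY[, t] <- alive & (u_y[, t - 1] < p)
          missX[, t] <- alive & (u_x[, t - 1] < p)
        })
    }
  }
  m$C <- C
  m$RY <- 1L - (missY | C == 1L)
  m$RX <- 1L - (missX | C == 1L)
  storage.mode(m$RY) <- "integer"
  storage.mode(m$RX) <- "integer"
  m$Y[m$RY == 0L] <- NA_real_
  m$X[m$RX == 0L] <- NA_real_
  m
}

realized_props <- function(m) {
  T_ <- m$T
  idx <- 2:T_
  mono <- mean(m$C[, idx] == 1L)
  nonmono <- mean((m$RX[, idx] == 0L | m$RY[, idx] == 0L) & m$C[, idx] == 0L)
  c(nonmono = nonmono, mono = mono)
}

#' Impose missing-at-random missingness on a complete panel
#'
#' Blanks outcome and/or time-varying-confounder cells at visits t >= 1
#' according to the scenario's pattern, with logistic missingness models
#' whose predictors are exclusively lagged quantities (previous
#' treatment, confounder, outcome, and the baseline covariates). Monotone
#' drop-out is drawn from a discrete-time hazard and propagated
#' absorbingly. Intercepts are taken from the shipped calibration (or
#' computed on demand) so the realized marginal proportions of
#' non-monotone and monotone missing person-visits match the scenario
#' targets to within one percentage point. Baseline (t = 0) is never
#' blanked and treatment is always fully recorded.
#'
#' @param panel a complete panel
#' @param spec a [scenario_spec()]
#' @param coeffs the [dgp_coefficients()] used to generate the panel
#' @param seed RNG seed
#' @return a panel with missing cells and updated indicators
#' @export
impose_missingness <- function(panel, spec, coeffs, seed) {
  validate_panel(panel, complete = TRUE)
  m <- panel_mats(panel)
  m$bz <- (m$b_cont - coeffs$b_cont$center) / coeffs$b_cont$scale
  icpt <- missingness_intercepts(spec, coeffs)
  set.seed(seed)
  T_ <- m$T
  u_drop <- matrix(stats::runif(m$n * (T_ - 1)), m$n)
  u_y <- matrix(stats::runif(m$n * (T_ - 1)), m$n)
  u_x <- matrix(stats::runif(m$n * (T_ - 1)), m$n)
  m <- apply_missingness(m, spec, coeffs, icpt, u_drop, u_y, u_x)
  validate_panel(mats_panel(m))
}

## intercept lookup: shipped config first, then in-session cache, then
## runtime calibration
.mimsm_cache <- new.env(parent = emptyenv())

intercept_key <- function(spec) {
  paste(spec$pattern, spec$level, spec$outcome_dist, spec$misspec, sep = "_")
}

missingness_intercepts <- function(spec, coeffs) {
  key <- intercept_key(spec)
  shipped <- coeffs$miss$intercepts[[key]]
  if (!is.null(shipped)) {
    return(list(nonmono = shipped$nonmonotone %||% -Inf,
                dropout = shipped$dropout %||% -Inf))
  }
  if (!is.null(.mimsm_cache[[key]])) return(.mimsm_cache[[key]])
  icpt <- calibrate_missingness_intercepts(spec, coeffs)
  .mimsm_cache[[key]] <- icpt
  icpt
}

#' Calibrate missingness-model intercepts
#'
#' Bisection on the drop-out and non-monotone model intercepts against a
#' large simulated cohort until the realized marginal proportions of
#' monotone and non-monotone missing person-visits (t >= 1) match the
#' scenario targets. The drop-out intercept is solved first (it is
#' unaffected by intermittent blanking); the non-monotone intercept is
#' then solved with drop-out in place, since intermittent missingness
#' only applies to cells not yet censored. A target of zero returns
#' `-Inf` (no missingness of that type). Deterministic given the internal
#' calibration seed.
#'
#' @param spec a [scenario_spec()]
#' @param coeffs a [dgp_coefficients()] object
#' @param n cohort size for calibration
#' @param seed internal calibration seed
#' @param tol tolerance on the realized proportions
#' @return list with elements `nonmono` and `dropout` (intercepts on the
#'   logit scale, `-Inf` meaning "never missing")
#' @export
calibrate_missingness_intercepts <- function(spec, coeffs, n = 50000, seed = 760613,
                                             tol = 0.002) {
  m <- gen_mats(n, coeffs, seed)
  m$bz <- (m$b_cont - coeffs$b_cont$center) / coeffs$b_cont$scale
  T_ <- m$T
  set.seed(seed + 1L)
  u_drop <- matrix(stats::runif(n * (T_ - 1)), n)
  u_y <- matrix(stats::runif(n * (T_ - 1)), n)
  u_x <- matrix(stats::runif(n * (T_ - 1)), n)
  bounds <- c(-20, 20)
  solve_icpt <- function(target, f) {
    if (target <= 0) return(-Inf)
    if (f(bounds[2]) < target)
      stop("missingness target ", target, " unreachable within intercept bounds [-20, 20]")
    stats::uniroot(function(i) f(i) - target, interval = bounds, tol = 1e-4)$root
  }
  i_drop <- solve_icpt(spec$mono_target, function(i) {
    mm <- apply_missingness(m, spec, coeffs, list(nonmono = -Inf, dropout = i),
                            u_drop, u_y, u_x)
    realized_props(mm)["mono"]
  })
  i_nm <- solve_icpt(spec$nonmono_target, function(i) {
    mm <- apply_missingness(m, spec, coeffs, list(nonmono = i, dropout = i_drop),
                            u_drop, u_y, u_x)
    realized_props(mm)["nonmono"]
  })
  icpt <- list(nonmono = i_nm, dropout = i_drop)
  chk <- apply_missingness(m, spec, coeffs, icpt, u_drop, u_y, u_x)
  pr <- realized_props(chk)
  if (abs(pr["nonmono"] - spec$nonmono_target) > max(tol, 0.005) ||
      abs(pr["mono"] - spec$mono_target) > max(tol, 0.005))
    stop("missingness calibration failed to reach targets: realized ",
         paste(signif(pr, 3), collapse = "/"))
  icpt
}
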