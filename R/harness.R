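## Simulation harness: factorial scenario grid, per-replication
## application of the competing missing-data approaches, and Monte-Carlo
## performance measures.

#' Estimation pipelines
#'
#' Three end-to-end estimators of the always-vs-never ATE on one panel:
#'
#' * `ate_complete()` - stabilized-treatment-weighted MSM on a complete
#'   panel (the reference estimator; guards the generator/estimator pair
#'   before the missing-data methods are compared).
#' * `ate_ipw()` - the weighting approach: censor at the first missing
#'   observation (monotonizing any intermittent missingness), fit
#'   treatment and missingness hazard models, multiply the stabilized
#'   weight sets, and fit the MSM on the persons observed throughout.
#' * `ate_mi()` - the imputation approach: multiple imputation by
#'   chained equations, then a stabilized-treatment-weighted MSM within
#'   each completed panel, pooled by Rubin's rules.
#'
#' @param panel a panel data frame
#' @return named vector `c(estimate, se, n_used)`
#' @export
ate_complete <- function(panel) {
  tm <- fit_treatment_models(panel)
  sw <- stabilized_treatment_weights(panel, tm)
  fit <- fit_msm(panel, sw)
  est <- ate_always_vs_never(fit)
  c(est, n_used = fit$n_ids)
}

#' @rdname ate_complete
#' @export
ate_ipw <- function(panel) {
  cen <- censor_after_first_missing(panel)
  tm <- fit_treatment_models(cen)
  sw <- stabilized_treatment_weights(cen, tm, na_action = "na")
  mm <- fit_missingness_models(cen)
  mw <- stabilized_missingness_weights(cen, mm)
  tw <- total_weights(sw, mw)
  fit <- fit_msm(cen, tw)
  est <- ate_always_vs_never(fit)
  c(est, n_used = fit$n_ids)
}

#' @rdname ate_complete
#' @param M imputations
#' @param n_iter chained-equation cycles
#' @param seed RNG seed for the imputation draws
#' @param method `"norm"` for linear-regression imputation throughout,
#'   `"pmm"` for predictive mean matching of the (skewed) outcome
#'   variables, the normally distributed confounder staying on linear
#'   imputation
#' @param predictors see [mice_run()]
#' @export
ate_mi <- function(panel, M = 50L, n_iter = 5L, seed = 1,
                   method = c("norm", "pmm"), predictors = "all") {
  method <- match.arg(method)
  mm <- if (method == "pmm") c(y = "pmm") else NULL
  stack <- mice_run(panel, method_map = mm, M = M, n_iter = n_iter,
                    seed = seed, predictors = predictors)
  ests <- matrix(NA_real_, 2, M, dimnames = list(c("estimate", "se"), NULL))
  tm <- NULL
  for (m in seq_len(M)) {
    cp <- stack$panels[[m]]
    tm <- fit_treatment_models(cp, start = tm)  # warm start across imputations
    sw <- stabilized_treatment_weights(cp, tm)
    fit <- fit_msm(cp, sw)
    ests[, m] <- ate_always_vs_never(fit)
  }
  pooled <- rubin_combine(ests["estimate", ], ests["se", ]^2)
  c(estimate = pooled$theta, se = sqrt(pooled$V), n_used = length(unique(panel$id)))
}

#' Run one simulation replication
#'
#' Generates a complete panel, imposes the scenario's missingness, and
#' applies each method to the same data: the complete-data reference
#' (before blanking), the weighting approach, and multiple imputation
#' (linear imputation always; predictive mean matching additionally in
#' skewed-outcome scenarios). Stage failures are recorded per method, not
#' raised.
#'
#' @param spec a [scenario_spec()]
#' @param rep_index replication number (seeds derive from
#'   `spec$base_seed + rep_index`)
#' @param coeffs optional [dgp_coefficients()]; defaults to the shipped
#'   calibrated set for the scenario's outcome distribution and
#'   misspecification level
#' @param methods subset of `c("complete_data_reference", "IPW",
#'   "MI_linear", "MI_PMM")`
#' @return data frame of one record per method
#' @export
run_replication <- function(spec, rep_index, coeffs = NULL, methods = NULL) {
  if (is.null(coeffs)) coeffs <- dgp_coefficients(spec$outcome_dist, spec$misspec)
  if (is.null(methods)) {
    methods <- c("complete_data_reference", "IPW", "MI_linear")
    if (spec$outcome_dist != "normal") methods <- c(methods, "MI_PMM")
  }
  seeds <- derive_seeds(spec$base_seed + rep_index, 3L)
  complete <- generate_complete_panel(spec, coeffs, seeds[1])
  observed <- impose_missingness(complete, spec, coeffs, seeds[2])

  one <- function(method) {
    t0 <- proc.time()[3]
    res <- tryCatch(
      switch(method,
        complete_data_reference = ate_complete(complete),
        IPW = ate_ipw(observed),
        MI_linear = ate_mi(observed, M = spec$M, n_iter = spec$n_iter,
                           seed = seeds[3], method = "norm"),
        MI_PMM = ate_mi(observed, M = spec$M, n_iter = spec$n_iter,
                        seed = seeds[3], method = "pmm"),
        stop("unknown method: ", method)),
      error = function(e) conditionMessage(e))
    el <- unname(proc.time()[3] - t0)
    if (is.character(res)) {
      data.frame(scenario = scenario_label(spec), rep = rep_index, method = method,
                 estimate = NA_real_, se = NA_real_, n_used = NA_real_,
                 error = res, seconds = el)
    } else {
      data.frame(scenario = scenario_label(spec), rep = rep_index, method = method,
                 estimate = unname(res["estimate"]), se = unname(res["se"]),
                 n_used = unname(res["n_used"]), error = NA_character_, seconds = el)
    }
  }
  do.call(rbind, lapply(methods, one))
}

#' Monte-Carlo performance measures
#'
#' Per method: mean estimate, bias, empirical SE (SD of the estimates),
#' root mean squared error, and Monte-Carlo standard errors of each.
#' `rmse^2 = bias^2 + emp_se^2 (R-1)/R` holds by construction.
#'
#' @param records replication records from [run_replication()]
#' @param true_ate the true value of the estimand
#' @return data frame, one row per scenario x method
#' @export
performance_table <- function(records, true_ate) {
  ok <- records[!is.na(records$estimate), ]
  sp <- split(ok, list(ok$scenario, ok$method), drop = TRUE)
  rows <- lapply(sp, function(d) {
    th <- d$estimate
    R <- length(th)
    bias <- mean(th) - true_ate
    emp_se <- stats::sd(th)
    sq <- (th - true_ate)^2
    rmse <- sqrt(mean(sq))
    data.frame(scenario = d$scenario[1], method = d$method[1], n_reps = R,
               mean_estimate = mean(th), bias = bias, emp_se = emp_se, rmse = rmse,
               mcse_bias = emp_se / sqrt(R),
               mcse_emp_se = emp_se / sqrt(2 * (R - 1)),
               mcse_rmse = stats::sd(sq) / (2 * rmse * sqrt(R)),
               mean_model_se = mean(d$se, na.rm = TRUE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run a full scenario
#'
#' Executes `spec$n_reps` replications with seeds derived from the
#' scenario's master seed, collects all replication records, and
#' aggregates them into a performance table. Scenarios where more than
#' 5\% of replications fail are flagged invalid (with a warning), never
#' silently dropped.
#'
#' @inheritParams run_replication
#' @param true_ate true ATE; defaults to the coefficient set's calibrated
#'   value
#' @param progress print a dot every 25 replications
#' @return object of class `scenario_result`: list with `spec`,
#'   `records`, `performance`, `valid`
#' @export
run_scenario <- function(spec, coeffs = NULL, methods = NULL, true_ate = NULL,
                         progress = FALSE) {
  if (is.null(coeffs)) coeffs <- dgp_coefficients(spec$outcome_dist, spec$misspec)
  if (is.null(true_ate)) true_ate <- coeffs$true_ate
  recs <- vector("list", spec$n_reps)
  for (r in seq_len(spec$n_reps)) {
    recs[[r]] <- run_replication(spec, r, coeffs, methods)
    if (progress && r %% 25 == 0) cat(".")
  }
  if (progress) cat("\n")
  records <- do.call(rbind, recs)
  fail_rate <- tapply(is.na(records$estimate), records$method, mean)
  valid <- all(fail_rate <= 0.05)
  if (!valid)
    warning("scenario ", scenario_label(spec), " flagged invalid: failure rate ",
            paste(names(fail_rate), signif(fail_rate, 2), sep = "=", collapse = ", "))
  structure(list(spec = spec, records = records,
                 performance = performance_table(records, true_ate),
                 true_ate = true_ate, valid = valid),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("<scenario_result> ", scenario_label(x$spec), "  true ATE =", x$true_ate, "\n")
  print(x$performance[, c("method", "n_reps", "mean_estimate", "bias", "emp_se", "rmse")],
        digits = 4)
  invisible(x)
}

#' The factorial scenario grid
#'
#' Emits the study's simulation cells: the normal-outcome cells (the four
#' single-pattern settings plus the mixed pattern, each at low and high
#' missingness), the four skewed-outcome cells (low/high skew by low/high
#' missingness, mixed pattern), and the two misspecification cells
#' (low/high omitted-interaction, mixed pattern at high missingness). At
#' full scale each cell runs n = 5000 persons, 1000 replications and
#' M = 50 imputations, and the normal-outcome cells are twinned at
#' n = 1000; the reduced scale (n = 1000, 200 replications, M = 10) is
#' the desk-sized reproduction used by the tests and the acceptance
#' script.
#'
#' @param scale `"reduced"` or `"full"`
#' @param base_seed master seed; each cell gets a distinct derived seed
#' @return list of [scenario_spec()]s
#' @export
scenario_grid <- function(scale = c("reduced", "full"), base_seed = 2023L) {
  scale <- match.arg(scale)
  sizes <- if (scale == "full") list(n = 5000L, n_reps = 1000L, M = 50L)
           else list(n = 1000L, n_reps = 200L, M = 10L)
  cells <- list()
  add <- function(pattern, level, outcome_dist = "normal", misspec = "none",
                  n = sizes$n) {
    i <- length(cells) + 1L
    cells[[i]] <<- scenario_spec(pattern = pattern, level = level,
                                 outcome_dist = outcome_dist, misspec = misspec,
                                 n = n, n_reps = sizes$n_reps, M = sizes$M,
                                 base_seed = base_seed + i * 100000L)
  }
  for (lev in c("low", "high"))
    for (pat in c("nm_outcome", "nm_confounder", "nm_both", "monotone", "mixed"))
      add(pat, lev)
  for (lev in c("low", "high"))
    for (d in c("skew_low", "skew_high"))
      add("mixed", lev, outcome_dist = d)
  for (ms in c("low", "high"))
    add("mixed", "high", misspec = ms)
  if (scale == "full")
    for (lev in c("low", "high"))
      for (pat in c("nm_outcome", "nm_confounder", "nm_both", "monotone", "mixed"))
        add(pat, lev, n = 1000L)
  cells
}

#' Reproducibility manifest for a scenario run
#'
#' Records everything needed to rerun a scenario bit-identically: the
#' scenario parameters (including the master seed, from which every
#' replication and stage seed derives), package version, method list and
#' per-method failure counts.
#'
#' @param result a `scenario_result`
#' @param path optional JSON output path
#' @return the manifest list, invisibly if written
#' @export
run_manifest <- function(result, path = NULL) {
  sp <- result$spec
  man <- list(
    package = "mimsm",
    version = as.character(utils::packageVersion("mimsm")),
    scenario = scenario_label(sp),
    spec = sp[c("pattern", "level", "outcome_dist", "misspec", "n", "n_reps",
                "M", "n_iter", "base_seed")],
    true_ate = result$true_ate,
    methods = unique(result$records$method),
    failures = as.list(tapply(is.na(result$records$estimate),
                              result$records$method, sum)),
    valid = result$valid
  )
  if (!is.null(path)) {
    jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(man))
  }
  man
}
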