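#' Define one simulation scenario
#'
#' A scenario is one cell of the factorial simulation design: a
#' missingness pattern, a missingness level, an outcome-noise
#' distribution, a degree of analysis-model misspecification, and the
#' replication sizes.
#'
#' @param pattern missingness pattern: `"nm_outcome"` (intermittent
#'   missing outcome), `"nm_confounder"` (intermittent missing
#'   time-varying confounder), `"nm_both"` (both missing jointly),
#'   `"monotone"` (drop-out only), `"mixed"` (independent intermittent
#'   missingness in outcome and confounder plus drop-out). All
#'   non-monotone patterns additionally include monotone drop-out, as in
#'   registry data where attrition coexists with item non-response.
#' @param level `"low"` (10\% non-monotone + 10\% monotone person-visits)
#'   or `"high"` (25\% + 25\%)
#' @param outcome_dist outcome-noise family, see [dgp_coefficients()]
#' @param misspec analysis-model misspecification degree
#' @param n persons per replication
#' @param n_reps number of replications
#' @param M number of imputations
#' @param n_iter chained-equation burn-in cycles
#' @param base_seed master seed for the scenario; per-replication seeds
#'   are derived from it
#' @return object of class `scenario_spec`
#' @export
scenario_spec <- function(pattern = c("nm_outcome", "nm_confounder", "nm_both",
                                      "monotone", "mixed"),
                          level = c("low", "high"),
                          outcome_dist = c("normal", "skew_low", "skew_high"),
                          misspec = c("none", "low", "high"),
                          n = 5000L, n_reps = 1000L, M = 50L, n_iter = 5L,
                          base_seed = 2023L) {
  pattern <- match.arg(pattern)
  level <- match.arg(level)
  outcome_dist <- match.arg(outcome_dist)
  misspec <- match.arg(misspec)
  stopifnot(n >= 1, n_reps >= 1, M >= 2, n_iter >= 1)
  prop <- if (level == "high") 0.25 else 0.10
  sp <- list(pattern = pattern, level = level, outcome_dist = outcome_dist,
             misspec = misspec, n = as.integer(n), n_reps = as.integer(n_reps),
             M = as.integer(M), n_iter = as.integer(n_iter),
             base_seed = as.integer(base_seed),
             nonmono_target = if (pattern == "monotone") 0 else prop,
             mono_target = prop,
             T = 5L)
  class(sp) <- "scenario_spec"
  sp
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("<scenario_spec> ", scenario_label(x), "\n", sep = "")
  cat("  n =", x$n, " reps =", x$n_reps, " M =", x$M,
      " base_seed =", x$base_seed, "\n")
  invisible(x)
}

#' @rdname scenario_spec
#' @param spec a `scenario_spec`
#' @export
scenario_label <- function(spec) {
  paste(spec$pattern, spec$level, spec$outcome_dist, spec$misspec, sep = "/")
}

#' Load scenarios and coefficients from a YAML config
#'
#' The config has an optional `coefficients` block (a path to a
#' coefficient YAML, otherwise the shipped calibrated defaults are used)
#' and a `scenarios` list whose entries mirror the [scenario_spec()]
#' arguments. Unknown keys and out-of-range values are rejected.
#'
#' @param path config file path
#' @return list with elements `specs` (list of `scenario_spec`) and
#'   `coefficients_config` (path passed to [dgp_coefficients()])
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  allowed_top <- c("coefficients", "scenarios")
  unknown <- setdiff(names(cfg), allowed_top)
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  coef_path <- cfg$coefficients
  allowed <- c("pattern", "level", "outcome_dist", "misspec", "n", "n_reps",
               "M", "n_iter", "base_seed")
  specs <- lapply(seq_along(cfg$scenarios), function(i) {
    sc <- cfg$scenarios[[i]]
    unknown <- setdiff(names(sc), allowed)
    if (length(unknown))
      stop("scenario ", i, ": unknown key(s): ", paste(unknown, collapse = ", "))
    ok <- tryCatch(do.call(scenario_spec, sc), error = function(e) e)
    if (inherits(ok, "error"))
      stop("scenario ", i, ": ", conditionMessage(ok))
    ok
  })
  list(specs = specs, coefficients_config = coef_path)
}
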