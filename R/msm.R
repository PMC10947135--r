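#' Fit the weighted marginal structural model
#'
#' Weighted least squares of the end-of-follow-up outcome on the
#' treatment history (one indicator per visit t = 1..T-1; baseline
#' treatment is structurally zero and carries no coefficient), using each
#' person's cumulative weight at the final visit. Persons with a missing
#' final outcome or weight do not contribute. The coefficient covariance
#' is the heteroscedasticity-robust (sandwich, HC0) estimator; with one
#' row per person this is also the id-clustered estimator.
#'
#' Because the stabilized-weight numerators condition on the baseline
#' covariates, the weighted outcome model must condition on them too
#' (otherwise baseline confounding re-enters through the stabilization);
#' the model therefore includes the baseline covariates as nuisance
#' terms by default. The treatment-history coefficients and their
#' always-vs-never sum are unaffected in expectation: with no
#' treatment-baseline effect modification the model remains correctly
#' specified and the estimand is the same marginal contrast.
#'
#' @param panel a panel data frame (complete, completed by imputation, or
#'   censored)
#' @param weights a `weight_vector`; the cumulative weight at the final
#'   visit is used. `NULL` fits an unweighted model.
#' @param baseline include the baseline covariates as nuisance terms
#'   (keep `TRUE` whenever the weight numerators condition on them)
#' @return object of class `msm_fit` with elements `alpha`, `beta`
#'   (per-visit treatment coefficients), `vcov` (treatment-coefficient
#'   block), `n_ids`, `weight_kind`
#' @export
fit_msm <- function(panel, weights = NULL, baseline = TRUE) {
  m <- panel_mats(panel)
  T_ <- m$T
  yT <- m$Y[, T_]
  if (is.null(weights)) {
    w <- rep(1, m$n)
    kind <- "unweighted"
  } else {
    wT <- weights[weights$t == T_ - 1L, ]
    w <- wT$cum_weight[match(m$ids, wT$id)]
    kind <- weights$kind[1]
  }
  use <- !is.na(yT) & !is.na(w) & w > 0
  if (!any(use)) stop("no usable persons: all final-visit outcomes or weights missing")
  A <- m$A[use, 2:T_, drop = FALSE]
  a_names <- paste0("a", 1:(T_ - 1L))
  colnames(A) <- a_names
  d <- data.frame(y = yT[use], A)
  if (baseline) {
    d$b_bin <- m$b_bin[use]
    d$bz <- (m$b_cont[use] - mean(m$b_cont)) / stats::sd(m$b_cont)
  }
  fit <- stats::lm(y ~ ., data = d, weights = w[use])
  cf <- stats::coef(fit)
  if (anyNA(cf[a_names]))
    stop("collinear treatment history columns (positivity problem: ",
         "some regimes unrepresented among usable persons)")
  ## near-singular meat warnings arise routinely with few usable ids and
  ## extreme weights; the point estimate is unaffected and the SE is
  ## reported as-is
  vc <- suppressWarnings(sandwich::vcovHC(fit, type = "HC0"))
  keep <- c("(Intercept)", a_names)
  out <- list(alpha = unname(cf[1]),
              beta = cf[a_names],
              vcov = vc[keep, keep],
              n_ids = sum(use),
              weight_kind = kind)
  class(out) <- "msm_fit"
  out
}

#' @export
print.msm_fit <- function(x, ...) {
  cat("<msm_fit> weights:", x$weight_kind, " persons:", x$n_ids, "\n")
  est <- ate_always_vs_never(x)
  cat("  beta:", paste(signif(x$beta, 4), collapse = " "), "\n")
  cat("  ATE (always vs never):", signif(est["estimate"], 4),
      " SE:", signif(est["se"], 4), "\n")
  invisible(x)
}

#' Always-treat vs never-treat contrast
#'
#' The estimand is the difference in mean end-of-follow-up outcome
#' between the "always treat" and "never treat" regimes, i.e. the sum of
#' the per-visit treatment coefficients. The standard error uses the
#' all-ones contrast on the coefficient covariance.
#'
#' @param fit an `msm_fit`
#' @return named numeric vector `c(estimate, se)`
#' @export
ate_always_vs_never <- function(fit) {
  k <- length(fit$beta)
  est <- sum(fit$beta)
  V <- fit$vcov[-1, -1, drop = FALSE]
  se <- sqrt(drop(rep(1, k) %*% V %*% rep(1, k)))
  c(estimate = est, se = se)
}

#' Nonparametric bootstrap interval for a full-pipeline ATE
#'
#' Resamples persons (ids) with replacement, reruns an arbitrary
#' estimation pipeline on each resample, and returns the percentile
#' interval. Intended for case-study-style analyses; simulation
#' performance is assessed from replication spread instead, the bootstrap
#' being too expensive to nest inside a simulation.
#'
#' @param panel a panel data frame
#' @param pipeline function taking a panel and returning a scalar ATE
#'   estimate
#' @param B_boot number of bootstrap resamples
#' @param seed RNG seed
#' @param conf confidence level
#' @return list with `lower`, `upper`, `estimates` (successful resample
#'   estimates) and `n_fail` (resamples whose pipeline errored, recorded
#'   and skipped)
#' @export
bootstrap_ci <- function(panel, pipeline, B_boot = 1000, seed = 1, conf = 0.95) {
  panel <- panel[order(panel$id, panel$t), ]
  T_ <- max(panel$t) + 1L
  ids <- unique(panel$id)
  n <- length(ids)
  row0 <- match(ids, panel$id)  # first row of each id block
  set.seed(seed)
  est <- rep(NA_real_, B_boot)
  for (b in seq_len(B_boot)) {
    pick <- sample.int(n, n, replace = TRUE)
    rows <- rep(row0[pick], each = T_) + rep(0:(T_ - 1L), n)
    bp <- panel[rows, ]
    bp$id <- rep(seq_len(n), each = T_)
    est[b] <- tryCatch(pipeline(bp), error = function(e) NA_real_)
  }
  ok <- est[!is.na(est)]
  if (!length(ok)) stop("pipeline failed in every bootstrap resample")
  alpha <- (1 - conf) / 2
  qs <- stats::quantile(ok, c(alpha, 1 - alpha), names = FALSE)
  list(lower = qs[1], upper = qs[2], estimates = ok, n_fail = sum(is.na(est)))
}
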