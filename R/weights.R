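## Pooled logistic weight models. All models are fitted by glm.fit on
## hand-built design matrices (visit indicators included), which keeps
## the per-replication cost low enough for the simulation harness.

## design matrix helpers ------------------------------------------------

## rows: visits t >= 1 of a sorted panel, with lagged columns attached
lagged_frame <- function(panel) {
  panel <- panel[order(panel$id, panel$t), ]
  T_ <- max(panel$t) + 1L
  stopifnot(nrow(panel) %% T_ == 0)
  cur <- panel$t >= 1L
  lag <- panel$t <= (T_ - 2L)
  out <- panel[cur, c("id", "t", "b_bin", "b_cont", "x", "a", "y", "r_x", "r_y")]
  out$a_lag <- panel$a[lag]
  out$x_lag <- panel$x[lag]
  out$y_lag <- panel$y[lag]
  out
}

visit_dummies <- function(t) {
  lv <- sort(unique(t))[-1]
  if (!length(lv)) return(NULL)
  m <- sapply(lv, function(v) as.numeric(t == v))
  colnames(m) <- paste0("visit", lv)
  m
}

fit_pooled_logistic <- function(X, y, what, start = NULL) {
  if (length(unique(y)) < 2L)
    stop("cannot fit ", what, " model: response has no variation")
  if (!is.null(start) && length(start) != ncol(X)) start <- NULL
  fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial(),
                                         start = start))
  p <- fit$fitted.values
  if (any(p < 1e-10) || any(p > 1 - 1e-10))
    stop("perfect separation in ", what, " model (fitted probabilities at 0/1)")
  fit$coefficients
}

## ----------------------------------------------------------------------

#' Fit pooled logistic treatment models
#'
#' Fits the numerator and denominator models of the stabilized treatment
#' weights by pooled logistic regression over visits t >= 1 (treatment at
#' baseline is structurally zero and carries no model). The denominator
#' regresses treatment on previous treatment, the current time-varying
#' confounder, the previous outcome and the baseline covariates; the
#' numerator on previous treatment and baseline covariates only. Both
#' include visit indicators. Rows with missing model covariates are
#' dropped (e.g. a censored panel); on a complete or completed panel all
#' person-visits contribute.
#'
#' @param panel a panel data frame
#' @param start optional warm start: a previous `treatment_models` fit on
#'   similar data (e.g. another completed panel of the same imputation
#'   stack), whose coefficients seed the iterative fits
#' @return object of class `treatment_models`
#' @export
fit_treatment_models <- function(panel, start = NULL) {
  lf <- lagged_frame(panel)
  bz_c <- mean(panel$b_cont); bz_s <- stats::sd(panel$b_cont)
  lf$bz <- (lf$b_cont - bz_c) / bz_s
  ok <- !is.na(lf$x) & !is.na(lf$y_lag)
  lf <- lf[ok, ]
  pa <- tapply(lf$a, lf$t, mean)
  if (any(pa == 0) || any(pa == 1))
    stop("positivity violation: treatment is constant at visit(s) ",
         paste(names(pa)[pa %in% c(0, 1)], collapse = ", "))
  V <- visit_dummies(lf$t)
  Xd <- cbind(intercept = 1, a_lag = lf$a_lag, x = lf$x, y_lag = lf$y_lag,
              b_bin = lf$b_bin, bz = lf$bz, V)
  Xn <- cbind(intercept = 1, a_lag = lf$a_lag, b_bin = lf$b_bin, bz = lf$bz, V)
  out <- list(den = fit_pooled_logistic(Xd, lf$a, "treatment denominator", start$den),
              num = fit_pooled_logistic(Xn, lf$a, "treatment numerator", start$num),
              bz_center = bz_c, bz_scale = bz_s,
              visits = sort(unique(lf$t)))
  class(out) <- "treatment_models"
  out
}

treatment_probs <- function(models, lf) {
  lf$bz <- (lf$b_cont - models$bz_center) / models$bz_scale
  V <- visit_dummies(lf$t)
  Xd <- cbind(1, lf$a_lag, lf$x, lf$y_lag, lf$b_bin, lf$bz, V)
  Xn <- cbind(1, lf$a_lag, lf$b_bin, lf$bz, V)
  list(den = expit(drop(Xd %*% models$den)), num = expit(drop(Xn %*% models$num)))
}

new_weight_vector <- function(id, t, p_num, p_den, ratio, cum, kind) {
  nr <- length(id)
  structure(list(id = id, t = t, p_num = rep_len(p_num, nr),
                 p_den = rep_len(p_den, nr), ratio = ratio, cum_weight = cum,
                 kind = rep_len(kind, nr)),
            class = c("weight_vector", "data.frame"),
            row.names = seq_len(nr))
}

## cumulative product within id over visits; input sorted by id, t and
## complete (T rows per id); NA ratios propagate to all later visits
cum_by_id <- function(ratio, n, T_) {
  m <- matrix(ratio, nrow = T_)
  for (t in 2:T_) m[t, ] <- m[t - 1L, ] * m[t, ]
  as.vector(m)
}

#' Stabilized inverse-probability-of-treatment weights
#'
#' For each person-visit, computes the ratio of the numerator to the
#' denominator model probability of the realized treatment, and the
#' cumulative product over visits. The baseline visit contributes ratio 1
#' (treatment there is deterministic).
#'
#' @param panel a panel data frame
#' @param models a `treatment_models` fit
#' @param na_action `"error"` aborts naming the first person-visit with a
#'   missing model covariate; `"na"` returns NA weights from that visit
#'   on (used for censored panels, where only fully observed ids need a
#'   final-visit weight)
#' @return a `weight_vector` data frame with per-visit and cumulative
#'   weights, kind `"treatment"`
#' @export
stabilized_treatment_weights <- function(panel, models, na_action = c("error", "na")) {
  na_action <- match.arg(na_action)
  panel <- panel[order(panel$id, panel$t), ]
  T_ <- max(panel$t) + 1L
  n <- nrow(panel) / T_
  lf <- lagged_frame(panel)
  bad <- is.na(lf$x) | is.na(lf$y_lag)
  if (any(bad) && na_action == "error") {
    i <- which(bad)[1]
    stop("missing treatment-model covariate at id ", lf$id[i], ", visit ", lf$t[i],
         "; impute or censor first")
  }
  pr <- treatment_probs(models, lf)
  p_den <- ifelse(lf$a == 1, pr$den, 1 - pr$den)
  p_num <- ifelse(lf$a == 1, pr$num, 1 - pr$num)
  ratio <- p_num / p_den
  ## interleave baseline ratio-1 rows
  full_ratio <- rep(1, n * T_)
  full_num <- full_den <- rep(NA_real_, n * T_)
  pos <- which(panel$t >= 1L)
  full_ratio[pos] <- ratio
  full_num[pos] <- p_num
  full_den[pos] <- p_den
  cum <- cum_by_id(full_ratio, n, T_)
  new_weight_vector(panel$id, panel$t, full_num, full_den, full_ratio, cum, "treatment")
}

#' Censor a panel at the first missing observation
#'
#' Marks every cell from the first visit with a missing outcome or
#' time-varying confounder onward as unobserved, regardless of whether
#' the missingness was monotone (drop-out) or intermittent. The result
#' has monotone missingness for every id, which is what the
#' inverse-probability-of-missingness weighting approach requires.
#'
#' @param panel a panel data frame
#' @return the monotonized panel
#' @export
censor_after_first_missing <- function(panel) {
  m <- panel_mats(panel)
  miss <- m$RX == 0L | m$RY == 0L
  first <- apply(miss, 1, function(r) if (any(r)) which(r)[1] else m$T + 1L)
  keep <- outer(first, seq_len(m$T), function(f, t) t < f)
  m$RX[!keep] <- 0L
  m$RY[!keep] <- 0L
  m$X[!keep] <- NA_real_
  m$Y[!keep] <- NA_real_
  mats_panel(m)
}

#' Fit pooled logistic missingness (observation) models
#'
#' On a monotonized panel (see [censor_after_first_missing()]), fits the
#' discrete-time hazard of remaining observed: among persons observed
#' through visit t-1, a pooled logistic model of the indicator "still
#' observed at t". The denominator conditions on previous treatment,
#' outcome, confounder and baseline covariates; the numerator on previous
#' treatment and baseline covariates. Visit indicators are included in
#' both. After monotonization the outcome and confounder indicators
#' coincide, so a single combined hazard is modelled.
#'
#' If the panel has no missingness the models are degenerate
#' (observation probability identically 1) and the resulting weights
#' equal 1, so the total weights reduce to the treatment weights.
#'
#' @param panel a monotonized panel
#' @return object of class `missingness_models`
#' @export
fit_missingness_models <- function(panel) {
  m <- panel_mats(panel)
  obs <- m$RX == 1L & m$RY == 1L
  ## monotone check: each indicator's observed cells must form a prefix
  is_prefix <- function(r) all(r == (seq_along(r) <= sum(r)))
  pref <- apply(m$RX == 1L, 1, is_prefix) & apply(m$RY == 1L, 1, is_prefix)
  if (!all(pref))
    stop("panel has non-monotone missingness; run censor_after_first_missing() first")
  lf <- lagged_frame(mats_panel(m))
  obs_lag <- as.vector(t(obs[, -m$T, drop = FALSE]))
  obs_cur <- as.vector(t(obs[, -1, drop = FALSE]))
  atrisk <- obs_lag
  lf <- lf[atrisk, ]
  r <- as.integer(obs_cur[atrisk])
  if (all(r == 1L)) {
    out <- list(degenerate = TRUE)
    class(out) <- "missingness_models"
    return(out)
  }
  bz_c <- mean(panel$b_cont); bz_s <- stats::sd(panel$b_cont)
  lf$bz <- (lf$b_cont - bz_c) / bz_s
  V <- visit_dummies(lf$t)
  Xd <- cbind(intercept = 1, a_lag = lf$a_lag, y_lag = lf$y_lag, x_lag = lf$x_lag,
              b_bin = lf$b_bin, bz = lf$bz, V)
  Xn <- cbind(intercept = 1, a_lag = lf$a_lag, b_bin = lf$b_bin, bz = lf$bz, V)
  out <- list(degenerate = FALSE,
              den = fit_pooled_logistic(Xd, r, "missingness denominator"),
              num = fit_pooled_logistic(Xn, r, "missingness numerator"),
              bz_center = bz_c, bz_scale = bz_s)
  class(out) <- "missingness_models"
  out
}

#' Stabilized inverse-probability-of-missingness weights
#'
#' Visit-level ratio of numerator to denominator probability of being
#' observed, cumulated over visits, for cells still observed; NA once a
#' person is censored (censored persons do not contribute to the
#' end-of-follow-up regression).
#'
#' @param panel a monotonized panel
#' @param models a `missingness_models` fit
#' @return a `weight_vector`, kind `"missingness"`
#' @export
stabilized_missingness_weights <- function(panel, models) {
  panel <- panel[order(panel$id, panel$t), ]
  T_ <- max(panel$t) + 1L
  n <- nrow(panel) / T_
  if (models$degenerate) {
    return(new_weight_vector(panel$id, panel$t, NA_real_, NA_real_,
                             rep(1, n * T_), rep(1, n * T_), "missingness"))
  }
  lf <- lagged_frame(panel)
  lf$bz <- (lf$b_cont - models$bz_center) / models$bz_scale
  V <- visit_dummies(lf$t)
  Xd <- cbind(1, lf$a_lag, lf$y_lag, lf$x_lag, lf$b_bin, lf$bz, V)
  Xn <- cbind(1, lf$a_lag, lf$b_bin, lf$bz, V)
  p_den <- expit(drop(Xd %*% models$den))
  p_num <- expit(drop(Xn %*% models$num))
  obs_cur <- lf$r_x == 1L & lf$r_y == 1L
  ratio <- ifelse(obs_cur, p_num / p_den, NA_real_)
  full_ratio <- rep(1, n * T_)
  full_num <- full_den <- rep(NA_real_, n * T_)
  pos <- which(panel$t >= 1L)
  full_ratio[pos] <- ratio
  full_num[pos] <- p_num
  full_den[pos] <- p_den
  cum <- cum_by_id(full_ratio, n, T_)
  new_weight_vector(panel$id, panel$t, full_num, full_den, full_ratio, cum, "missingness")
}

#' Total weights
#'
#' Elementwise product of stabilized treatment and missingness weights on
#' an identical (id, t) support. Several missingness weight vectors (e.g.
#' separate outcome and confounder indicators in user data) all multiply
#' in.
#'
#' @param sw a `weight_vector` of treatment weights
#' @param ... one or more `weight_vector`s of missingness weights
#' @return a `weight_vector`, kind `"total"`
#' @export
total_weights <- function(sw, ...) {
  mws <- list(...)
  cum <- sw$cum_weight
  ratio <- sw$ratio
  for (mw in mws) {
    if (!identical(mw$id, sw$id) || !identical(mw$t, sw$t))
      stop("weight vectors are not on the same (id, t) support")
    cum <- cum * mw$cum_weight
    ratio <- ratio * mw$ratio
  }
  new_weight_vector(sw$id, sw$t, NA_real_, NA_real_, ratio, cum, "total")
}

#' @export
print.weight_vector <- function(x, ...) {
  cat("<weight_vector> kind:", x$kind[1], " cells:", nrow(x), "\n")
  wT <- x$cum_weight[x$t == max(x$t)]
  cat("  final-visit cum weight: mean", signif(mean(wT, na.rm = TRUE), 4),
      " sd", signif(stats::sd(wT, na.rm = TRUE), 4),
      " max", signif(max(wT, na.rm = TRUE), 4), "\n")
  invisible(x)
}
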