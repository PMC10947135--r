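## Multiple imputation by chained equations, in wide format (one row per
## person, time-indexed columns), so that measurements both before and
## after a missing cell inform its imputation.

#' Draw imputation-model parameters from their posterior
#'
#' Fits ordinary least squares on the complete cases, then perturbs the
#' parameters to propagate estimation uncertainty into the imputations:
#' the residual variance is drawn as sigma2* = sigma2_hat * (n_obs - k) / g
#' with g a chi-squared draw on n_obs - k degrees of freedom, and the
#' coefficients as beta* ~ N(beta_hat, sigma2* (X'X)^-1).
#'
#' Collinear design columns are dropped with a warning (their beta*
#' entries are zero so downstream matrix products are unaffected).
#' Noiseless data (zero residual variance) yield sigma2* = 0 and
#' beta* = beta_hat exactly.
#'
#' @param y_obs response on the complete cases
#' @param design_obs design matrix (including intercept column) on the
#'   complete cases
#' @param seed optional RNG seed; `NULL` uses the current RNG stream
#' @return object of class `imputation_model_draw` with fields
#'   `beta_hat`, `sigma2_hat`, `sigma2_star`, `beta_star`, `n_obs`, `k`,
#'   `g`, `kept` (retained column indices)
#' @export
draw_posterior_params <- function(y_obs, design_obs, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- as.matrix(design_obs)
  n <- length(y_obs)
  p <- ncol(X)
  kept <- seq_len(p)
  R <- tryCatch(chol(crossprod(X)), error = function(e) NULL)
  if (is.null(R)) {
    qx <- qr(X)
    if (qx$rank < p) {
      drop_idx <- qx$pivot[(qx$rank + 1L):p]
      warning("dropping ", length(drop_idx), " collinear imputation-model column(s): ",
              paste(colnames(X)[drop_idx], collapse = ", "))
      kept <- sort(qx$pivot[seq_len(qx$rank)])
      X <- X[, kept, drop = FALSE]
    }
    R <- chol(crossprod(X))
  }
  k <- ncol(X)
  if (n <= k) stop("imputation model needs more complete cases (", n, ") than parameters (", k, ")")
  Xty <- crossprod(X, y_obs)
  beta_hat <- backsolve(R, forwardsolve(t(R), Xty))
  rss <- sum((y_obs - drop(X %*% beta_hat))^2)
  sigma2_hat <- rss / (n - k)
  if (sigma2_hat < 1e-12) {
    sigma2_star <- 0
    beta_star <- beta_hat
    g <- NA_real_
  } else {
    g <- stats::rchisq(1, n - k)
    sigma2_star <- sigma2_hat * (n - k) / g
    beta_star <- beta_hat + sqrt(sigma2_star) * backsolve(R, stats::rnorm(k))
  }
  full <- function(b) { v <- numeric(p); v[kept] <- b; v }
  structure(list(beta_hat = full(beta_hat), sigma2_hat = sigma2_hat,
                 sigma2_star = sigma2_star, beta_star = full(beta_star),
                 n_obs = n, k = k, g = g, kept = kept),
            class = "imputation_model_draw")
}

#' Linear-regression imputation
#'
#' Imputes missing cells as beta* x + eps*, with eps* independent
#' Normal(0, sigma2*) draws.
#'
#' @param draw an `imputation_model_draw`
#' @param design_miss design matrix of the cases to impute
#' @param seed optional RNG seed
#' @return numeric vector of imputed values
#' @export
impute_linear <- function(draw, design_miss, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- as.matrix(design_miss)
  mu <- drop(X %*% draw$beta_star)
  if (draw$sigma2_star == 0) return(mu)
  mu + stats::rnorm(nrow(X), 0, sqrt(draw$sigma2_star))
}

#' Logistic-regression imputation for binary variables
#'
#' Fits a logistic model on the complete cases, draws coefficients from
#' their asymptotic normal distribution, and imputes Bernoulli draws with
#' probability expit(beta* x). Perfect separation falls back to a
#' ridge-penalized fit (logged via a warning).
#'
#' @param y_obs 0/1 response on the complete cases
#' @param design_obs design matrix on the complete cases
#' @param design_miss design matrix of the cases to impute
#' @param seed optional RNG seed
#' @return integer vector of imputed 0/1 values
#' @export
impute_logistic <- function(y_obs, design_obs, design_miss, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- as.matrix(design_obs)
  fit <- suppressWarnings(stats::glm.fit(X, y_obs, family = stats::binomial()))
  p_fit <- fit$fitted.values
  if (any(p_fit < 1e-10) || any(p_fit > 1 - 1e-10)) {
    warning("separation in logistic imputation model; using ridge-penalized fit")
    lambda <- 1e-3
    Xa <- rbind(X, sqrt(lambda) * diag(ncol(X)))
    ya <- c(y_obs, rep(0.5, ncol(X)))
    fit <- suppressWarnings(stats::glm.fit(Xa, ya, family = stats::binomial()))
    p_fit <- fit$fitted.values[seq_along(y_obs)]
  }
  beta_hat <- fit$coefficients
  W <- p_fit * (1 - p_fit)
  XtWX <- crossprod(X * sqrt(W))
  R <- chol(XtWX)
  beta_star <- beta_hat + backsolve(R, stats::rnorm(ncol(X)))
  p_imp <- expit(drop(as.matrix(design_miss) %*% beta_star))
  stats::rbinom(length(p_imp), 1L, p_imp)
}

## donor matching for PMM: q nearest observed predicted means per missing
## case (ties at the q-th distance included), one donor sampled uniformly
pmm_match <- function(pred_obs, y_obs, pred_miss, q) {
  n_obs <- length(pred_obs)
  n_miss <- length(pred_miss)
  q <- min(q, n_obs)
  o <- order(pred_obs)
  po <- pred_obs[o]
  yo <- y_obs[o]
  pos <- findInterval(pred_miss, po)
  ## the q nearest sorted positions lie within [pos - q + 1, pos + q]
  offs <- (-q + 1L):q
  w <- length(offs)
  idx <- outer(pos, offs, "+")
  idx[idx < 1L] <- 1L
  idx[idx > n_obs] <- n_obs
  d <- abs(matrix(po[idx], n_miss) - pred_miss)
  ## boundary clamping duplicates adjacent indices; knock them out so a
  ## donor never counts twice toward the q nearest
  if (w > 1L) {
    dup <- cbind(FALSE, idx[, -1L, drop = FALSE] == idx[, -w, drop = FALSE])
    d[dup] <- Inf
  }
  ## row-wise sort via one global order call
  o <- order(row(d), d)
  d_sorted <- matrix(d[o], nrow = n_miss, byrow = TRUE)
  dq <- d_sorted[, q]
  cand <- d <= dq                      # ties at the q-th distance included
  k <- rowSums(cand)
  target <- ceiling(stats::runif(n_miss) * k)
  ## column of the target-th candidate per row, via row cumulative counts
  cum <- cand %*% upper.tri(matrix(0, w, w), diag = TRUE)
  sel <- cand & (cum == target)
  col <- max.col(sel, ties.method = "first")
  yo[idx[cbind(seq_len(n_miss), col)]]
}

#' Predictive-mean-matching imputation
#'
#' Computes predicted means beta* x for the observed cases and for each
#' case to impute, identifies the `q` observed cases whose predicted
#' means are closest, and imputes the observed response of one of them
#' chosen at random. Ties at the q-th distance are all included before
#' sampling. Every imputed value is therefore an element of the observed
#' values, so the imputations inherit the shape (skewness, support) of
#' the observed distribution.
#'
#' @param draw an `imputation_model_draw`
#' @param design_obs design matrix on the complete cases
#' @param y_obs observed responses (donor pool)
#' @param design_miss design matrix of the cases to impute
#' @param q number of donors
#' @param seed optional RNG seed
#' @return numeric vector of imputed values, a subset of `y_obs`
#' @export
impute_pmm <- function(draw, design_obs, y_obs, design_miss, q = 5L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(q >= 1, length(y_obs) >= 1)
  pred_obs <- drop(as.matrix(design_obs) %*% draw$beta_star)
  pred_miss <- drop(as.matrix(design_miss) %*% draw$beta_star)
  pmm_match(pred_obs, y_obs, pred_miss, as.integer(q))
}

## ---------------------------------------------------------------------
## chained equations driver
## ---------------------------------------------------------------------

## wide representation: one row per person with columns
## b_bin, bz, a1..a{T-1}, x0..x{T-1}, y0..y{T-1}
panel_wide <- function(panel) {
  m <- panel_mats(panel)
  T_ <- m$T
  W <- cbind(b_bin = m$b_bin, bz = standardize(m$b_cont),
             m$A[, -1, drop = FALSE], m$X, m$Y)
  colnames(W) <- c("b_bin", "bz", paste0("a", 1:(T_ - 1L)),
                   paste0("x", 0:(T_ - 1L)), paste0("y", 0:(T_ - 1L)))
  list(W = W, mats = m)
}

## predictor columns for one target variable
predictor_cols <- function(target, cols, mode) {
  if (mode == "all") return(setdiff(cols, target))
  ## "matched": lagged treatment, confounder and outcome history only,
  ## mirroring the missingness-weight models
  v <- sub("^[axy]", "", target)
  t_i <- as.integer(v)
  kind <- substr(target, 1, 1)
  a_max <- if (kind == "y") t_i else t_i - 1L
  keep <- c("b_bin", "bz",
            if (a_max >= 1L) paste0("a", 1:a_max),
            paste0("x", 0:(t_i - 1L)),
            paste0("y", 0:(t_i - 1L)),
            if (kind == "y") paste0("x", t_i))
  intersect(cols, keep)
}

#' Multiple imputation by chained equations on a longitudinal panel
#'
#' Reshapes the panel to wide format (time-indexed columns), then imputes
#' each incomplete variable cyclically from a conditional model given the
#' other variables: Bayesian linear regression (`"norm"`),
#' predictive mean matching (`"pmm"`) for continuous variables, logistic
#' regression (`"logreg"`) for binary ones. Each of the `M` imputations
#' starts from random draws of the observed margins and runs `n_iter`
#' burn-in cycles. Non-imputed cells are bit-identical across the M
#' completed panels.
#'
#' A drifting-chain heuristic (imputed-variable means moving
#' monotonically across all cycles) raises a warning, not an error.
#'
#' @param panel a panel with missing x/y cells
#' @param method_map named character vector mapping wide-format variable
#'   names (e.g. `"y3"`) or the shorthands `"x"`/`"y"` (all visits) to an
#'   imputation method; default `"norm"` for everything
#' @param M number of imputations (>= 2)
#' @param n_iter chained-equation cycles per imputation
#' @param seed master seed; per-imputation sub-seeds are derived from it
#' @param predictors `"all"` (every other time-indexed variable predicts
#'   each incomplete one) or `"matched"` (lagged treatment/confounder/
#'   outcome history only, mirroring the missingness-weight models)
#' @param q donors for predictive mean matching
#' @return object of class `imputation_stack`: list of `M` completed
#'   panels plus the method map and sub-seeds
#' @export
mice_run <- function(panel, method_map = NULL, M = 50L, n_iter = 5L, seed = 1,
                     predictors = c("all", "matched"), q = 5L) {
  predictors <- match.arg(predictors)
  stopifnot(M >= 2)
  pw <- panel_wide(panel)
  W <- pw$W
  cols <- colnames(W)
  miss_by_col <- colSums(is.na(W))
  incomplete <- cols[miss_by_col > 0]
  sub_seeds <- derive_seeds(seed, M)

  if (!length(incomplete)) {
    panels <- replicate(M, panel, simplify = FALSE)
    return(structure(list(panels = panels, sub_seeds = sub_seeds,
                          method_map = character(), n_iter = n_iter,
                          predictors = predictors),
                     class = "imputation_stack"))
  }

  ## resolve methods
  methods <- stats::setNames(rep("norm", length(incomplete)), incomplete)
  binary <- vapply(incomplete, function(v) all(W[, v] %in% c(0, 1, NA)), logical(1))
  methods[binary] <- "logreg"
  if (!is.null(method_map)) {
    for (nm in names(method_map)) {
      hit <- if (nm %in% incomplete) nm else grep(paste0("^", nm, "[0-9]+$"), incomplete, value = TRUE)
      methods[hit] <- method_map[[nm]]
    }
  }
  ## impute in visit order (x then y within visit)
  ord <- order(as.integer(sub("^[axy]", "", incomplete)),
               match(substr(incomplete, 1, 1), c("x", "y", "a")))
  incomplete <- incomplete[ord]
  pred_sets <- lapply(incomplete, predictor_cols, cols = cols, mode = predictors)
  names(pred_sets) <- incomplete
  miss_rows <- lapply(incomplete, function(v) which(is.na(W[, v])))
  names(miss_rows) <- incomplete

  run_one <- function(s) {
    set.seed(s)
    Wm <- W
    for (v in incomplete) {   # initialize from observed margins
      mr <- miss_rows[[v]]
      obs <- W[-mr, v]
      Wm[mr, v] <- obs[sample.int(length(obs), length(mr), replace = TRUE)]
    }
    chain_means <- matrix(NA_real_, n_iter, length(incomplete))
    for (it in seq_len(n_iter)) {
      for (j in seq_along(incomplete)) {
        v <- incomplete[j]
        mr <- miss_rows[[v]]
        pc <- pred_sets[[v]]
        Xall <- cbind(1, Wm[, pc, drop = FALSE])
        Xo <- Xall[-mr, , drop = FALSE]
        Xm <- Xall[mr, , drop = FALSE]
        yo <- W[-mr, v]
        imp <- switch(methods[[v]],
          norm = {
            dr <- draw_posterior_params(yo, Xo)
            impute_linear(dr, Xm)
          },
          pmm = {
            dr <- draw_posterior_params(yo, Xo)
            impute_pmm(dr, Xo, yo, Xm, q = q)
          },
          logreg = impute_logistic(yo, Xo, Xm),
          stop("unknown imputation method: ", methods[[v]]))
        Wm[mr, v] <- imp
        chain_means[it, j] <- mean(imp)
      }
    }
    if (n_iter >= 6) {
      drift <- apply(chain_means, 2, function(m) all(diff(m) > 0) || all(diff(m) < 0))
      if (any(drift))
        warning("imputation chain means drifting monotonically for: ",
                paste(incomplete[drift], collapse = ", "), call. = FALSE)
    }
    Wm
  }

  panel_sorted <- panel[order(panel$id, panel$t), ]
  T_ <- pw$mats$T
  xcols <- paste0("x", 0:(T_ - 1L)); ycols <- paste0("y", 0:(T_ - 1L))
  panels <- lapply(sub_seeds, function(s) {
    Wm <- run_one(s)
    cp <- panel_sorted
    cp$x <- as.vector(t(Wm[, xcols]))
    cp$y <- as.vector(t(Wm[, ycols]))
    cp
  })
  structure(list(panels = panels, sub_seeds = sub_seeds, method_map = methods,
                 n_iter = n_iter, predictors = predictors),
            class = "imputation_stack")
}

#' @export
print.imputation_stack <- function(x, ...) {
  cat("<imputation_stack> M =", length(x$panels),
      " iterations =", x$n_iter, " predictors =", x$predictors, "\n")
  if (length(x$method_map))
    cat("  methods:", paste(names(x$method_map), x$method_map, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Pool estimates across imputations by Rubin's rules
#'
#' The pooled estimate is the mean of the per-imputation estimates; the
#' total variance combines the within-imputation variance W (mean of the
#' per-imputation variances) and the between-imputation variance B
#' (sample variance of the estimates) as V = W + (1 + 1/M) B.
#'
#' @param estimates per-imputation point estimates (length M >= 2)
#' @param variances per-imputation variances (same length, >= 0)
#' @return object of class `pooled_estimate` with `theta`, `W`, `B`, `V`,
#'   `M`, `df` (Rubin's large-sample degrees of freedom) and a `ci()`
#'   via [confint.pooled_estimate()]
#' @export
rubin_combine <- function(estimates, variances) {
  M <- length(estimates)
  if (M < 2) stop("Rubin's rules need M >= 2 (between-imputation variance undefined)")
  stopifnot(length(variances) == M, all(variances >= 0))
  theta <- mean(estimates)
  W <- mean(variances)
  B <- stats::var(estimates)
  V <- W + (1 + 1 / M) * B
  r <- (1 + 1 / M) * B / W
  df <- if (B == 0 || !is.finite(r)) Inf else (M - 1) * (1 + 1 / r)^2
  structure(list(theta = theta, W = W, B = B, V = V, M = M, df = df),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat("<pooled_estimate> theta =", signif(x$theta, 5),
      " SE =", signif(sqrt(x$V), 4), " (M =", x$M, ")\n")
  cat("  W =", signif(x$W, 4), " B =", signif(x$B, 4), " V =", signif(x$V, 4), "\n")
  invisible(x)
}

#' Confidence interval for a pooled estimate
#' @param object a `pooled_estimate`
#' @param parm ignored
#' @param level confidence level
#' @param ... ignored
#' @export
confint.pooled_estimate <- function(object, parm, level = 0.95, ...) {
  q <- stats::qt(1 - (1 - level) / 2, df = object$df)
  c(object$theta - q * sqrt(object$V), object$theta + q * sqrt(object$V))
}
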