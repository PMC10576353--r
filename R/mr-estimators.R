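mr_result <- function(method, beta_causal, se, n_instruments, extra = list()) {
  res <- c(list(
    method = method,
    beta_causal = beta_causal,
    se = se,
    or_point = exp(beta_causal),
    ci_low = exp(beta_causal - Z95 * se),
    ci_high = exp(beta_causal + Z95 * se),
    p_value = 2 * stats::pnorm(-abs(beta_causal / se)),
    n_instruments = n_instruments
  ), extra)
  structure(res, class = "mr_result")
}

#' @export
print.mr_result <- function(x, digits = 3, ...) {
  cat(sprintf("MR estimate (%s, %d instrument%s)\n", x$method,
              x$n_instruments, if (x$n_instruments == 1L) "" else "s"))
  cat(sprintf("  log-OR per exposure SD: %.*f (SE %.*f)\n",
              digits + 2, x$beta_causal, digits + 2, x$se))
  cat(sprintf("  OR: %.*f (95%% CI %.*f, %.*f), p = %.3g\n",
              digits, x$or_point, digits, x$ci_low, digits, x$ci_high,
              x$p_value))
  if (x$method == "egger") {
    cat(sprintf("  Egger intercept: %.*f (SE %.*f), pleiotropy p = %.3g\n",
                digits + 2, x$egger_intercept, digits + 2,
                x$egger_intercept_se, x$pleiotropy_p))
  }
  invisible(x)
}

set_vectors <- function(set) {
  if (!inherits(set, "instrument_set")) {
    stop("expected an instrument_set", call. = FALSE)
  }
  ins <- set$instruments
  list(bx = ins$beta_exposure, sx = ins$se_exposure,
       by = ins$beta_outcome, sy = ins$se_outcome,
       k = nrow(ins))
}

#' Wald ratio estimate from a single instrument
#'
#' Causal log-OR per exposure SD as the ratio of the outcome to the
#' exposure coefficient, `beta_Y / beta_X`, with the first-order delta
#' method standard error `SE_Y / |beta_X|`.  The optional second-order
#' delta term adds the contribution of the exposure coefficient's
#' uncertainty.
#'
#' @param set An [instrument_set()]; must contain exactly one instrument
#'   unless `snp` selects one.
#' @param snp Optional variant id selecting the instrument.
#' @param second_order If `TRUE`, use the second-order delta-method SE
#'   `sqrt(SE_Y^2/beta_X^2 + beta_Y^2 SE_X^2 / beta_X^4)`.  Default
#'   `FALSE` (first-order).
#' @return An object of class `mr_result`.
#' @export
mr_wald <- function(set, snp = NULL, second_order = FALSE) {
  ins <- set$instruments
  if (!is.null(snp)) {
    idx <- match(snp, ins$snp)
    if (is.na(idx)) stop("variant not in set: ", snp, call. = FALSE)
    ins <- ins[idx, , drop = FALSE]
  }
  if (nrow(ins) != 1L) {
    stop("Wald ratio requires exactly one instrument; use `snp` to select",
         call. = FALSE)
  }
  bx <- ins$beta_exposure; by <- ins$beta_outcome
  sx <- ins$se_exposure; sy <- ins$se_outcome
  if (bx == 0) stop("beta_exposure is zero: Wald ratio undefined",
                    call. = FALSE)
  beta <- by / bx
  se <- if (second_order) {
    sqrt(sy^2 / bx^2 + by^2 * sx^2 / bx^4)
  } else {
    sy / abs(bx)
  }
  mr_result("wald", beta, se, 1L)
}

#' Fixed-effects inverse-variance-weighted MR estimate
#'
#' Weighted average of per-instrument Wald ratios with weights
#' `(beta_X / SE_Y)^2`, equivalently weighted least squares of `beta_Y`
#' on `beta_X` through the origin:
#' `beta = sum(bx * by / sy^2) / sum(bx^2 / sy^2)`,
#' `SE = 1 / sqrt(sum(bx^2 / sy^2))`.
#'
#' @param set An [instrument_set()] with at least one instrument.  Any
#'   correlation matrix is ignored (see [mr_ivw_correlated()]).
#' @param overdispersion If `TRUE`, apply a multiplicative
#'   random-effects scale `max(1, sigma_hat)` to the SE, where
#'   `sigma_hat^2` is the weighted residual mean square (requires >= 2
#'   instruments).  Default `FALSE`: fixed-effects weighting.
#' @return An object of class `mr_result`.
#' @export
mr_ivw <- function(set, overdispersion = FALSE) {
  v <- set_vectors(set)
  if (v$k < 1L) stop("empty instrument set", call. = FALSE)
  w <- v$bx^2 / v$sy^2
  beta <- sum(v$bx * v$by / v$sy^2) / sum(w)
  se <- 1 / sqrt(sum(w))
  if (overdispersion && v$k >= 2L) {
    resid <- v$by - beta * v$bx
    sigma2 <- sum(resid^2 / v$sy^2) / (v$k - 1)
    se <- se * max(1, sqrt(sigma2))
  }
  mr_result("ivw", beta, se, v$k)
}

#' Correlated-instrument IVW estimate (generalized least squares)
#'
#' Generalized weighted least squares of `beta_Y` on `beta_X` through
#' the origin with outcome covariance `Omega = D rho D`,
#' `D = diag(SE_Y)` and `rho` the instrument correlation matrix:
#' `beta = (X' Omega^-1 X)^-1 X' Omega^-1 Y`,
#' `SE = (X' Omega^-1 X)^-1/2`.  With an identity correlation matrix
#' this reduces exactly to [mr_ivw()].
#'
#' @param set An [instrument_set()] whose `correlation` matrix is
#'   present and positive definite.
#' @return An object of class `mr_result`.
#' @export
mr_ivw_correlated <- function(set) {
  v <- set_vectors(set)
  rho <- set$correlation
  if (is.null(rho)) {
    stop("instrument set carries no correlation matrix", call. = FALSE)
  }
  d <- v$sy
  omega <- rho * tcrossprod(d)
  ch <- tryCatch(chol(omega), error = function(e) {
    stop("correlation matrix is not positive definite", call. = FALSE)
  })
  # solve via the Cholesky factor for numerical stability
  xw <- backsolve(ch, v$bx, transpose = TRUE)
  yw <- backsolve(ch, v$by, transpose = TRUE)
  xtx <- sum(xw^2)
  beta <- sum(xw * yw) / xtx
  se <- 1 / sqrt(xtx)
  mr_result("ivw_correlated", beta, se, v$k)
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome on exposure coefficients with a
#' free intercept, weights `1/SE_Y^2`, after orienting every instrument
#' so that `beta_X >= 0` (both coefficients of a negative-exposure
#' instrument are sign-flipped; the fit is invariant to this choice of
#' orientation only through the intercept, which is why it is fixed by
#' convention).  The slope is the causal log-OR; a non-zero intercept
#' indicates directional horizontal pleiotropy.
#'
#' Standard errors are scaled by the multiplicative factor
#' `max(1, sigma_hat)` with `sigma_hat^2` the weighted residual sum of
#' squares over `k - 2` (the common overdispersion-truncation
#' convention); `se_type = "fixed"` disables the scaling.  P-values use
#' the normal reference by default; `p_reference = "t"` uses a
#' t-distribution on `k - 2` degrees of freedom.
#'
#' @param set An [instrument_set()] with at least three instruments.
#' @param se_type `"truncated"` (default, `max(1, sigma_hat)` scaling)
#'   or `"fixed"`.
#' @param p_reference `"normal"` (default) or `"t"`.
#' @param intercept If `FALSE`, the intercept is constrained to zero,
#'   in which case the slope reproduces [mr_ivw()] exactly (used for
#'   internal consistency checks).
#' @return An object of class `mr_result` with additional fields
#'   `egger_intercept`, `egger_intercept_se`, `pleiotropy_p`.
#' @export
mr_egger <- function(set, se_type = c("truncated", "fixed"),
                     p_reference = c("normal", "t"),
                     intercept = TRUE) {
  se_type <- match.arg(se_type)
  p_reference <- match.arg(p_reference)
  v <- set_vectors(set)
  if (intercept && v$k < 3L) {
    stop("MR-Egger requires at least 3 instruments", call. = FALSE)
  }
  flip <- sign(v$bx)
  flip[flip == 0] <- 1
  bx <- v$bx * flip
  by <- v$by * flip
  w <- 1 / v$sy^2

  X <- if (intercept) cbind(intercept = 1, slope = bx) else
    cbind(slope = bx)
  xtwx <- crossprod(X, X * w)
  xtwy <- crossprod(X, by * w)
  coefs <- drop(solve(xtwx, xtwy))
  covmat <- solve(xtwx)
  fitted <- drop(X %*% coefs)
  df_resid <- v$k - ncol(X)
  sigma2 <- if (df_resid > 0) sum(w * (by - fitted)^2) / df_resid else 0
  scale <- if (se_type == "truncated") max(1, sqrt(sigma2)) else 1

  slope <- coefs[["slope"]]
  slope_se <- sqrt(covmat["slope", "slope"]) * scale
  pfun <- function(stat) {
    if (p_reference == "t" && df_resid > 0) {
      2 * stats::pt(-abs(stat), df = df_resid)
    } else {
      2 * stats::pnorm(-abs(stat))
    }
  }
  extra <- list()
  if (intercept) {
    int <- coefs[["intercept"]]
    int_se <- sqrt(covmat["intercept", "intercept"]) * scale
    extra <- list(egger_intercept = int,
                  egger_intercept_se = int_se,
                  pleiotropy_p = pfun(int / int_se))
  }
  res <- mr_result(if (intercept) "egger" else "ivw", slope, slope_se,
                   v$k, extra)
  res$p_value <- pfun(slope / slope_se)
  res
}

#' Cochran Q heterogeneity test between independent estimates
#'
#' Inverse-variance heterogeneity statistic
#' `Q = sum(w_i (b_i - b_pooled)^2)` with `w_i = 1/se_i^2` and the
#' fixed-effect pooled mean `b_pooled`, referred to a chi-square
#' distribution on `length(beta) - 1` degrees of freedom.  Used in this
#' package to test heterogeneity of per-SD estimates between sexes
#' (two strata, 1 df).
#'
#' @param beta Numeric vector of log-OR estimates (length >= 2).
#' @param se Positive standard errors, same length.
#' @return A list of class `heterogeneity_test` with `q_statistic`,
#'   `df`, `p_value`, and the pooled estimate `beta_pooled`.
#' @export
heterogeneity_q <- function(beta, se) {
  if (length(beta) < 2L) {
    stop("need at least 2 estimates", call. = FALSE)
  }
  if (length(se) != length(beta) || any(se <= 0)) {
    stop("se must be positive and match beta in length", call. = FALSE)
  }
  w <- 1 / se^2
  pooled <- sum(w * beta) / sum(w)
  q <- sum(w * (beta - pooled)^2)
  df <- length(beta) - 1L
  structure(list(q_statistic = q, df = df,
                 p_value = stats::pchisq(q, df, lower.tail = FALSE),
                 beta_pooled = pooled),
            class = "heterogeneity_test")
}

#' @export
print.heterogeneity_test <- function(x, ...) {
  cat(sprintf("Heterogeneity Q = %.4g on %d df, p = %.4g\n",
              x$q_statistic, x$df, x$p_value))
  invisible(x)
}

#' Reconstruct a log-OR and its SE from a printed OR and 95% CI
#'
#' Convenience for feeding published odds/rate ratios into
#' [heterogeneity_q()]: the log-OR is `log(or)` and the SE is the CI
#' width on the log scale divided by `2 * 1.959964`.
#'
#' @param or Point estimate (odds or rate ratio).
#' @param ci_low,ci_high 95% confidence bounds.
#' @return A list with `beta` and `se`.
#' @export
log_or_from_ci <- function(or, ci_low, ci_high) {
  list(beta = log(or), se = (log(ci_high) - log(ci_low)) / (2 * Z95))
}
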