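#' Conditional logistic regression on matched case-control sets
#'
#' Fits the conditional likelihood
#' `prod_sets exp(x_case' b) / sum_members exp(x' b)` for matched
#' case-control data, the standard model for incidence-density sampled
#' nested case-control studies; under that sampling the exponentiated
#' coefficients estimate incidence rate ratios and can be read as
#' relative risks.  The maximization is delegated to
#' [survival::clogit()] (exact conditional likelihood); for 1:1 sets
#' the fit coincides with no-intercept logistic regression on
#' case-minus-control covariate differences, an identity exercised by
#' the package's test suite.
#'
#' Covariates constant within every matched set (the matching factors)
#' are absorbed by the conditioning and do not influence the fit.
#'
#' @param data `data.frame` of subjects.
#' @param covariates Character vector of covariate column names, or a
#'   one-sided formula giving the covariate terms.
#' @param set Set-identifier column (default `"set_id"`).
#' @param case Case-indicator column (default `"is_case"`).
#' @return A list of class `clogit_fit` with `coefficients`,
#'   `covariance`, `log_likelihood`, `null_log_likelihood`,
#'   `converged`, `n_sets_informative`, and the underlying survival
#'   fit as `fit`.
#' @examples
#' d <- data.frame(set_id = rep(1:3, each = 2),
#'                 is_case = rep(c(1, 0), 3),
#'                 x = c(1, 0, 1, 0, 0, 1))
#' f <- clogit_fit(d, "x")
#' exp(coef(f))  # rate-ratio estimate: 2
#' @export
clogit_fit <- function(data, covariates, set = "set_id",
                       case = "is_case") {
  terms_str <- if (inherits(covariates, "formula")) {
    attr(stats::terms(covariates), "term.labels")
  } else {
    covariates
  }
  if (length(terms_str) == 0L) {
    stop("at least one covariate is required", call. = FALSE)
  }
  validate_matched_sets(data, set = set, case = case)

  plain <- terms_str[terms_str %in% names(data)]
  informative <- vapply(split(seq_len(nrow(data)), data[[set]]),
                        function(idx) {
                          any(vapply(plain, function(cv) {
                            vals <- data[[cv]][idx]
                            length(unique(vals[!is.na(vals)])) > 1L
                          }, logical(1)))
                        }, logical(1))
  if (length(plain) > 0L && !any(informative)) {
    stop("no informative sets: case and controls identical on all ",
         "covariates", call. = FALSE)
  }

  # conditional logistic likelihood == stratified Cox exact partial
  # likelihood with unit follow-up times
  data[["..futime"]] <- rep(1, nrow(data))
  fml <- stats::as.formula(paste0(
    "survival::Surv(..futime, ", case, ") ~ ",
    paste(terms_str, collapse = " + "),
    " + survival::strata(", set, ")"))
  environment(fml) <- environment()
  warned <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = data, method = "exact"),
    warning = function(w) {
      warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  vc <- fit$var
  dimnames(vc) <- list(names(stats::coef(fit)), names(stats::coef(fit)))
  converged <- !warned && all(is.finite(stats::coef(fit))) &&
    all(is.finite(sqrt(pmax(diag(vc), 0)))) &&
    all(abs(stats::coef(fit)) < 15)

  structure(list(coefficients = stats::coef(fit),
                 covariance = vc,
                 log_likelihood = fit$loglik[2],
                 null_log_likelihood = fit$loglik[1],
                 converged = converged,
                 n_sets_informative = sum(informative),
                 formula = fml,
                 fit = fit),
            class = "clogit_fit")
}

#' @export
coef.clogit_fit <- function(object, ...) object$coefficients

#' @export
vcov.clogit_fit <- function(object, ...) object$covariance

#' @export
logLik.clogit_fit <- function(object, ...) {
  structure(object$log_likelihood,
            df = length(object$coefficients), class = "logLik")
}

#' Summarize a conditional-logistic fit as rate ratios
#'
#' @param object A [clogit_fit()] result.
#' @param ... Unused.
#' @return `data.frame` with log-RR, SE, RR, 95% CI, and Wald p per
#'   coefficient.
#' @export
summary.clogit_fit <- function(object, ...) {
  b <- object$coefficients
  se <- sqrt(diag(object$covariance))
  data.frame(term = names(b),
             estimate = unname(b),
             se = unname(se),
             rr = exp(unname(b)),
             ci_low = exp(unname(b) - Z95 * se),
             ci_high = exp(unname(b) + Z95 * se),
             p_value = 2 * stats::pnorm(-abs(unname(b) / se)),
             row.names = NULL)
}

#' @export
print.clogit_fit <- function(x, ...) {
  cat(sprintf(
    "Conditional logistic fit: %d informative set(s), logLik = %.3f%s\n",
    x$n_sets_informative, x$log_likelihood,
    if (x$converged) "" else "  [NOT CONVERGED]"))
  print(summary(x), digits = 4)
  invisible(x)
}

#' Likelihood ratio test between nested conditional-logistic fits
#'
#' `p` is the upper chi-square tail of `2 (ll_full - ll_reduced)` on
#' the difference in coefficient counts.  Used for interaction
#' product-term tests and fractional-polynomial non-linearity tests.
#'
#' @param full,reduced [clogit_fit()] objects, `reduced` nested in
#'   `full`.
#' @return A list with `statistic`, `df`, `p_value`.
#' @export
lrt <- function(full, reduced) {
  df <- length(full$coefficients) - length(reduced$coefficients)
  if (df < 1L) stop("full model must have more coefficients than reduced",
                    call. = FALSE)
  stat <- 2 * (full$log_likelihood - reduced$log_likelihood)
  if (stat < -1e-6) {
    stop("full model has lower likelihood than reduced: models are not ",
         "nested or did not converge", call. = FALSE)
  }
  stat <- max(stat, 0)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

fp_terms <- function(x, powers) {
  one <- function(p) if (p == 0) log(x) else x^p
  if (length(powers) == 1L) {
    m <- cbind(one(powers))
    colnames(m) <- paste0("fp", powers)
  } else if (powers[1] == powers[2]) {
    m <- cbind(one(powers[1]), one(powers[1]) * log(x))
    colnames(m) <- paste0("fp", powers[1], c("", ".log"))
  } else {
    m <- cbind(one(powers[1]), one(powers[2]))
    colnames(m) <- paste0("fp", powers)
  }
  m
}

#' Fractional-polynomial test of non-linearity in a matched design
#'
#' Searches first-degree fractional polynomials (FP1) over the standard
#' power grid `{-2, -1, -0.5, 0, 0.5, 1, 2, 3}` (0 meaning `log x`) and
#' second-degree pairs (FP2; a repeated power `p` contributes `x^p` and
#' `x^p log x`) for the exposure inside [clogit_fit()], holding the
#' adjustment covariates fixed.  Non-linearity is judged by a
#' likelihood ratio test of the best FP2 model against the linear
#' model on 3 degrees of freedom.  Exposures with non-positive values
#' are shifted to be strictly positive before transformation.
#'
#' @param data `data.frame` of subjects.
#' @param exposure Exposure column name.
#' @param adjustment Character vector of adjustment covariates
#'   (default none).
#' @param set,case Column names as in [clogit_fit()].
#' @return A list with `best_fp1`, `best_fp2` (selected powers),
#'   `p_nonlinearity`, and the fitted log-likelihoods
#'   (`loglik_linear`, `loglik_fp1`, `loglik_fp2`).
#' @export
fractional_polynomial_test <- function(data, exposure,
                                       adjustment = character(),
                                       set = "set_id", case = "is_case") {
  grid <- c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)
  x <- data[[exposure]]
  if (anyNA(x)) stop("exposure contains missing values", call. = FALSE)
  if (min(x) <= 0) x <- x - min(x) + 1e-6 + stats::sd(x) * 0.01
  if (min(x) <= 0) stop("exposure not positive after shift", call. = FALSE)

  fit_with <- function(powers) {
    m <- fp_terms(x, powers)
    d2 <- data
    nm <- paste0("..fp", seq_len(ncol(m)))
    for (j in seq_len(ncol(m))) d2[[nm[j]]] <- m[, j]
    clogit_fit(d2, c(nm, adjustment), set = set, case = case)
  }

  linear <- fit_with(1)
  fp1 <- lapply(grid, fit_with)
  ll1 <- vapply(fp1, function(f) f$log_likelihood, numeric(1))
  best1 <- grid[which.max(ll1)]

  pairs <- list()
  for (i in seq_along(grid)) {
    for (j in i:length(grid)) {
      pairs[[length(pairs) + 1L]] <- c(grid[i], grid[j])
    }
  }
  ll2 <- vapply(pairs, function(pw) fit_with(pw)$log_likelihood,
                numeric(1))
  best2 <- pairs[[which.max(ll2)]]

  stat <- max(0, 2 * (max(ll2) - linear$log_likelihood))
  list(best_fp1 = best1,
       best_fp2 = best2,
       p_nonlinearity = stats::pchisq(stat, 3, lower.tail = FALSE),
       loglik_linear = linear$log_likelihood,
       loglik_fp1 = max(ll1),
       loglik_fp2 = max(ll2))
}
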