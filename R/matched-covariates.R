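#' A-body-shape index (ABSI)
#'
#' `ABSI = WC(mm) * weight(kg)^(-2/3) * height(m)^(5/6)`, with waist
#' circumference and height supplied in the cohort's native cm and
#' converted internally.  ABSI was designed as a body-shape measure
#' approximately independent of BMI.
#'
#' @param waist Waist circumference in cm.
#' @param weight Weight in kg.
#' @param height Height in cm.
#' @return The index value (vectorized).
#' @examples
#' absi(89, 75, 167)
#' @export
absi <- function(waist, weight, height) {
  if (any(waist <= 0, na.rm = TRUE) || any(weight <= 0, na.rm = TRUE) ||
      any(height <= 0, na.rm = TRUE)) {
    stop("waist, weight, and height must all be positive", call. = FALSE)
  }
  (waist * 10) * weight^(-2 / 3) * (height / 100)^(5 / 6)
}

#' BMI- and height-adjusted waist circumference residuals
#'
#' Ordinary least squares of waist circumference on BMI and height
#' (with intercept) over complete cases; each subject receives their
#' residual.  Subjects with missing waist receive the sex-specific
#' median residual and are flagged as imputed — the simple-imputation
#' rule used when a study center lacks waist measurements.  Using
#' residuals rather than raw waist circumference avoids collinearity
#' with BMI and height in the disease model.
#'
#' @param data `data.frame` of subjects.
#' @param response Waist column name (default `"waist"`).
#' @param predictors Columns to adjust for (default `c("bmi", "height")`).
#' @param sex Sex column name used for median imputation (default
#'   `"sex"`).
#' @param impute If `FALSE`, missing-waist subjects keep `NA`
#'   (complete-case sensitivity mode).
#' @return `data.frame` with columns `residual` and `imputed`, one row
#'   per subject in input order.
#' @export
covariate_residuals <- function(data, response = "waist",
                                predictors = c("bmi", "height"),
                                sex = "sex", impute = TRUE) {
  y <- data[[response]]
  X <- as.matrix(data[, predictors, drop = FALSE])
  cc <- stats::complete.cases(cbind(y, X))
  if (sum(cc) < length(predictors) + 1L) {
    stop("need at least ", length(predictors) + 1L,
         " subjects with complete data", call. = FALSE)
  }
  Xc <- cbind(1, X[cc, , drop = FALSE])
  if (qr(Xc)$rank < ncol(Xc)) {
    stop("degenerate design: constant predictor(s)", call. = FALSE)
  }
  fit <- stats::lm.fit(Xc, y[cc])
  residual <- rep(NA_real_, nrow(data))
  residual[cc] <- fit$residuals
  imputed <- rep(FALSE, nrow(data))
  if (impute && any(!cc)) {
    med <- tapply(residual[cc], data[[sex]][cc], stats::median)
    miss <- which(!cc)
    residual[miss] <- med[as.character(data[[sex]][miss])]
    imputed[miss] <- TRUE
  }
  data.frame(residual = residual, imputed = imputed)
}

#' Sex-specific biomarker quintiles with control-based cut-offs
#'
#' Computes, per sex, the 20/40/60/80th percentiles of the biomarker
#' among control subjects (linear-interpolation empirical quantiles by
#' default), assigns every subject a quintile category using half-open
#' intervals `[low, high)` (top interval closed above by infinity;
#' when tied cut-offs make categories degenerate, ties resolve to the
#' lowest category), and attaches the control-median trend score of
#' each subject's (sex, quintile) cell.  The overall control standard
#' deviation is recorded as the per-SD scaling constant.
#'
#' @param data `data.frame` of subjects with at least the value, sex,
#'   and case columns.
#' @param value Biomarker column name (default `"biomarker"`).
#' @param sex Sex column name (default `"sex"`).
#' @param case Case-indicator column name (default `"is_case"`).
#' @param quantile_type Empirical quantile rule passed to
#'   [stats::quantile()] (default 7, linear interpolation).
#' @return A list of class `quintile_scheme` with per-sex `cutoffs` and
#'   `medians`, `control_sd`, and an `assignment` data.frame
#'   (`quintile`, `trend_score`) aligned with `data`.
#' @export
assign_quintiles <- function(data, value = "biomarker", sex = "sex",
                             case = "is_case", quantile_type = 7) {
  v <- data[[value]]
  sx <- as.character(data[[sex]])
  ctrl <- !as.logical(data[[case]])
  sexes <- sort(unique(sx))
  cutoffs <- list()
  medians <- list()
  quintile <- integer(nrow(data))
  trend <- rep(NA_real_, nrow(data))

  for (s in sexes) {
    cv <- v[ctrl & sx == s]
    cv <- cv[!is.na(cv)]
    if (length(unique(cv)) < 5L &&
        length(unique(cv)) > 1L) {
      stop("fewer than 5 distinct control values for sex '", s, "'",
           call. = FALSE)
    }
    if (length(cv) == 0L) {
      stop("no controls for sex '", s, "'", call. = FALSE)
    }
    cuts <- stats::quantile(cv, probs = c(0.2, 0.4, 0.6, 0.8),
                            type = quantile_type, names = FALSE)
    idx_s <- which(sx == s)
    u <- unique(cuts)
    q <- if (length(u) < 4L) {
      # degenerate (tied) cut-offs: resolve ties downward
      findInterval(v[idx_s], u, left.open = TRUE) + 1L
    } else {
      findInterval(v[idx_s], cuts) + 1L   # [low, high) intervals
    }
    quintile[idx_s] <- q
    med <- vapply(1:5, function(j) {
      vals <- v[idx_s][ctrl[idx_s] & q == j]
      if (length(vals) == 0L) NA_real_ else stats::median(vals)
    }, numeric(1))
    trend[idx_s] <- med[q]
    cutoffs[[s]] <- cuts
    medians[[s]] <- med
  }

  structure(list(cutoffs = cutoffs, medians = medians,
                 control_sd = stats::sd(v[ctrl], na.rm = TRUE),
                 assignment = data.frame(quintile = quintile,
                                         trend_score = trend)),
            class = "quintile_scheme")
}

#' Scale biomarker values by the control standard deviation
#'
#' Expresses raw biomarker concentrations in per-control-SD units, the
#' scale on which continuous relative risks are reported.
#'
#' @param values Raw biomarker values.
#' @param scheme A [assign_quintiles()] result, or a single positive
#'   number giving the control SD directly.
#' @return `values / control_sd`.
#' @export
standardize_by_control_sd <- function(values, scheme) {
  s <- if (inherits(scheme, "quintile_scheme")) scheme$control_sd else scheme
  if (!is.numeric(s) || length(s) != 1L || is.na(s) || s <= 0) {
    stop("control SD must be a single positive number", call. = FALSE)
  }
  values / s
}

#' Validate matched case-control sets
#'
#' Checks that every set identifier labels exactly one case and at
#' least one control.
#'
#' @param data `data.frame` of subjects.
#' @param set Set-identifier column (default `"set_id"`).
#' @param case Case-indicator column (default `"is_case"`).
#' @return `data`, invisibly; errors on malformed sets.
#' @export
validate_matched_sets <- function(data, set = "set_id",
                                  case = "is_case") {
  cases <- tapply(as.logical(data[[case]]), data[[set]], sum)
  sizes <- tapply(data[[case]], data[[set]], length)
  bad <- names(cases)[cases != 1L | sizes < 2L]
  if (length(bad) > 0L) {
    stop("malformed matched set(s): ",
         paste(utils::head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) " ..." else "", call. = FALSE)
  }
  invisible(data)
}

#' Drop matched sets by subject-level exclusion
#'
#' Applies a subject-level exclusion (e.g. prevalent diabetes, or
#' diagnosis within two years of recruitment) at the set level:
#' whenever the excluded subject is the set's case, the whole set
#' (case and matched controls) is removed; an excluded control is
#' removed individually, and sets left without any control are then
#' dropped too.
#'
#' @param data `data.frame` of subjects.
#' @param exclude Logical vector aligned with `data` rows flagging
#'   subjects to exclude.
#' @param set,case Column names as in [validate_matched_sets()].
#' @return The filtered `data.frame`; attribute `"n_sets_dropped"`
#'   counts fully removed sets.
#' @export
exclude_matched_sets <- function(data, exclude, set = "set_id",
                                 case = "is_case") {
  stopifnot(length(exclude) == nrow(data))
  excluded_case_sets <- unique(data[[set]][exclude & as.logical(data[[case]])])
  keep <- !exclude & !(data[[set]] %in% excluded_case_sets)
  out <- data[keep, , drop = FALSE]
  # drop sets left without a control
  n_ctrl <- tapply(!as.logical(out[[case]]), out[[set]], sum)
  empty <- names(n_ctrl)[n_ctrl == 0L]
  out <- out[!(out[[set]] %in% empty), , drop = FALSE]
  attr(out, "n_sets_dropped") <-
    length(unique(data[[set]])) - length(unique(out[[set]]))
  rownames(out) <- NULL
  out
}

#' Bonferroni adjustment with an explicit test count
#'
#' `min(1, p * n_tests)`; the test count is supplied explicitly because
#' the correction is applied across families of related tests (e.g.
#' a correlation panel, or a table of MR contrasts) rather than across
#' the p-values actually passed in.
#'
#' @param p P-value(s).
#' @param n_tests Number of tests in the family.
#' @return Adjusted p-value(s).
#' @export
bonferroni <- function(p, n_tests) {
  stopifnot(n_tests >= 1)
  pmin(1, p * n_tests)
}

#' Spearman partial correlation
#'
#' Ranks both variables (average ranks for ties), residualizes the
#' ranks on the covariates by least squares (with intercept), and
#' returns the Pearson correlation of the rank residuals together with
#' its t-based p-value on `n - 2 - q` degrees of freedom (`q` the
#' number of covariates).  With no covariates this is the ordinary
#' Spearman correlation.
#'
#' @param x,y Numeric vectors.
#' @param covariates Optional `data.frame`/matrix of control variables
#'   (e.g. age and sex coded numerically).
#' @return A list with `r`, `p_value`, `n`, `df`.
#' @export
spearman_partial <- function(x, y, covariates = NULL) {
  cc <- stats::complete.cases(x, y,
                              if (is.null(covariates)) rep(TRUE, length(x))
                              else covariates)
  x <- x[cc]; y <- y[cc]
  n <- length(x)
  q <- 0L
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("x and y must be non-constant", call. = FALSE)
  }
  rx <- rank(x); ry <- rank(y)
  if (!is.null(covariates)) {
    Z <- as.matrix(as.data.frame(covariates)[cc, , drop = FALSE])
    storage.mode(Z) <- "double"
    q <- ncol(Z)
    if (n <= q + 2L) stop("need n > number of covariates + 2",
                          call. = FALSE)
    Zi <- cbind(1, Z)
    rx <- stats::lm.fit(Zi, rx)$residuals
    ry <- stats::lm.fit(Zi, ry)$residuals
  }
  r <- stats::cor(rx, ry)
  df <- n - 2L - q
  tstat <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df)
  list(r = r, p_value = p, n = n, df = df)
}
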