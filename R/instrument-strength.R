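#' Variance in the exposure explained by a variant
#'
#' Two estimators of the per-variant proportion of trait variance
#' explained from GWAS summary statistics, for a trait expressed in SD
#' units:
#'
#' * `"se_based"` (default): `beta^2 / (beta^2 + n * SE^2)`, requiring
#'   the per-variant sample size.  This is the estimator whose
#'   three-variant total is consistent with the packaged study's
#'   printed total variance explained and F-statistic.
#' * `"eaf_based"`: `2 p (1 - p) beta^2` with `p` the effect-allele
#'   frequency, valid when beta is in trait-SD units.
#'
#' Both are vectorized over variants.
#'
#' @param beta Per-allele effect(s) in trait-SD units.
#' @param se Standard error(s); required for `"se_based"`.
#' @param n GWAS sample size(s); required for `"se_based"`.
#' @param eaf Effect-allele frequency(ies); required for `"eaf_based"`.
#' @param method `"se_based"` or `"eaf_based"`.
#' @return Numeric vector of per-variant variance fractions.
#' @export
variance_explained <- function(beta, se = NULL, n = NULL, eaf = NULL,
                               method = c("se_based", "eaf_based")) {
  method <- match.arg(method)
  if (method == "se_based") {
    if (is.null(se) || anyNA(se)) {
      stop("method 'se_based' requires 'se'", call. = FALSE)
    }
    if (is.null(n) || anyNA(n)) {
      stop("method 'se_based' requires 'n'", call. = FALSE)
    }
    beta^2 / (beta^2 + n * se^2)
  } else {
    if (is.null(eaf) || anyNA(eaf)) {
      stop("method 'eaf_based' requires 'eaf'", call. = FALSE)
    }
    2 * eaf * (1 - eaf) * beta^2
  }
}

#' Instrument-strength F-statistic
#'
#' `F = ((n - k - 1) / k) * (R2 / (1 - R2))` for `k` instruments jointly
#' explaining a fraction `R2` of the exposure variance in a GWAS of
#' size `n`.  Values above 10 conventionally indicate instruments not
#' subject to weak-instrument bias.
#'
#' @param r2_total Total variance explained, in `[0, 1)`.
#' @param n GWAS sample size (`n > k + 1`).
#' @param k Number of instruments.
#' @return The F-statistic (non-negative scalar).
#' @export
f_statistic <- function(r2_total, n, k) {
  if (r2_total < 0 || r2_total >= 1) {
    stop("r2_total must lie in [0, 1)", call. = FALSE)
  }
  if (n <= k + 1 || k < 1) {
    stop("need n > k + 1 >= 2", call. = FALSE)
  }
  ((n - k - 1) / k) * (r2_total / (1 - r2_total))
}

#' Summarize instrument strength for a set of exposure associations
#'
#' Convenience wrapper combining [variance_explained()] (summed over
#' variants) and [f_statistic()].
#'
#' @param assocs Exposure GWAS table (see [read_gwas_table()]); the `n`
#'   column may be overridden by `n`.
#' @param n GWAS sample size; defaults to the table's `n` column.
#' @param method Passed to [variance_explained()].
#' @return A list of class `instrument_strength` with
#'   `r2_per_variant`, `r2_total`, `f_statistic`, `n`, `k`.
#' @export
instrument_strength <- function(assocs, n = NULL,
                                method = c("se_based", "eaf_based")) {
  method <- match.arg(method)
  if (is.null(n)) n <- assocs$n
  r2 <- variance_explained(beta = assocs$beta, se = assocs$se, n = n,
                           eaf = assocs$eaf, method = method)
  r2_total <- sum(r2)
  k <- nrow(assocs)
  n1 <- if (length(unique(n)) == 1L) n[1] else max(n)
  structure(list(r2_per_variant = stats::setNames(r2, assocs$snp),
                 r2_total = r2_total,
                 f_statistic = f_statistic(r2_total, n1, k),
                 n = n1, k = k),
            class = "instrument_strength")
}

#' @export
print.instrument_strength <- function(x, ...) {
  cat(sprintf("Instrument strength: k = %d, n = %d\n", x$k, x$n))
  cat(sprintf("  R2 total = %.4f%% , F = %.1f\n", 100 * x$r2_total,
              x$f_statistic))
  invisible(x)
}

mr_power_scale <- function(n_cases, n_controls, r2) {
  n_total <- n_cases + n_controls
  phi <- n_cases / n_total
  sqrt(n_total * phi * (1 - phi) * r2)
}

#' Minimal detectable odds ratio for binary-outcome MR
#'
#' Smallest OR per exposure SD detectable at a two-sided level `alpha`
#' with the target `power`, given a case-control outcome sample and the
#' fraction of exposure variance explained by the instruments:
#' `log OR_min = (z_{1-alpha/2} + z_{power}) /
#'   sqrt(N phi (1 - phi) R2)` with `N = n_cases + n_controls` and
#' `phi = n_cases / N`.
#'
#' @param n_cases,n_controls Outcome sample counts.
#' @param r2 Instrument variance explained, in `(0, 1)`.
#' @param alpha Two-sided significance level (default 0.05).
#' @param power Target power (default 0.8).
#' @return The minimal detectable odds ratio (> 1).
#' @export
minimal_detectable_or <- function(n_cases, n_controls, r2,
                                  alpha = 0.05, power = 0.8) {
  stopifnot(n_cases > 0, n_controls > 0, alpha > 0, alpha < 1,
            power > 0, power < 1)
  if (r2 <= 0 || r2 >= 1) {
    stop("r2 must lie in (0, 1)", call. = FALSE)
  }
  lor <- (stats::qnorm(1 - alpha / 2) + stats::qnorm(power)) /
    mr_power_scale(n_cases, n_controls, r2)
  exp(lor)
}

#' Power to detect a candidate odds ratio in binary-outcome MR
#'
#' Inverse of [minimal_detectable_or()]:
#' `power = Phi(log(OR) sqrt(N phi (1 - phi) R2) - z_{1-alpha/2})`.
#'
#' @param or Candidate odds ratio per exposure SD (> 1).
#' @param n_cases,n_controls Outcome sample counts.
#' @param r2 Instrument variance explained, in `(0, 1)`.
#' @param alpha Two-sided significance level (default 0.05).
#' @return The power (probability).
#' @export
power_at_or <- function(or, n_cases, n_controls, r2, alpha = 0.05) {
  stopifnot(or > 0, r2 > 0, r2 < 1)
  stats::pnorm(log(or) * mr_power_scale(n_cases, n_controls, r2) -
                 stats::qnorm(1 - alpha / 2))
}
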