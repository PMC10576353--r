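#' Parameters for the two-sample GWAS summary-statistic simulator
#'
#' Defaults emulate the instrument panel of the packaged study: three
#' variants with allele frequencies and relative effect sizes matching
#' the published instruments, rescaled so that they jointly explain
#' `target_r2` (1%) of exposure variance, an exposure GWAS of 20,436,
#' and an outcome case-control sample of 58,131 cases and 67,347
#' controls.
#'
#' @param ... Named overrides: `k`, `eaf`, `beta_pattern` (relative
#'   per-allele exposure effects), `target_r2` (set `NULL` to use
#'   `beta_pattern` as-is), `n_exposure`, `n_cases`, `n_controls`,
#'   `theta` (true causal log-OR per exposure SD), `pleiotropy`
#'   (per-variant direct log-OR effects on the outcome, default zero),
#'   `seed`.
#' @return A list of class `gwas_sim_params`.
#' @export
gwas_sim_params <- function(...) {
  p <- list(
    k = 3L,
    eaf = c(0.13, 0.97, 0.01),
    beta_pattern = c(0.11, 0.26, -0.59),
    target_r2 = 0.01,
    n_exposure = 20436L,
    n_cases = 58131L,
    n_controls = 67347L,
    theta = 0.1,
    pleiotropy = NULL,
    seed = NULL
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(p))
  if (length(unknown) > 0L) {
    stop("unknown GWAS simulation parameter(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  p[names(over)] <- over
  p$k <- length(p$eaf)
  if (length(p$beta_pattern) != p$k) {
    stop("beta_pattern must match eaf in length", call. = FALSE)
  }
  if (any(p$eaf <= 0 | p$eaf >= 1)) {
    stop("allele frequencies must lie strictly in (0, 1)", call. = FALSE)
  }
  if (is.null(p$pleiotropy)) p$pleiotropy <- numeric(p$k)
  structure(p, class = "gwas_sim_params")
}

per_snp_ols <- function(g, y) {
  n <- length(y)
  gc <- g - mean(g)
  yc <- y - mean(y)
  sxx <- sum(gc^2)
  bhat <- sum(gc * yc) / sxx
  sse <- sum(yc^2) - bhat^2 * sxx
  se <- sqrt(sse / (n - 2) / sxx)
  c(beta = bhat, se = se)
}

per_snp_logistic <- function(g, y) {
  X <- cbind(1, g)
  fit <- stats::glm.fit(X, y, family = stats::binomial())
  mu <- fit$fitted.values
  cov <- solve(crossprod(X, X * (mu * (1 - mu))))
  c(beta = unname(fit$coefficients[2]), se = sqrt(cov[2, 2]))
}

#' Simulate two-sample GWAS summary statistics with known causal effect
#'
#' Generates two non-overlapping samples with genotypes
#' `Binomial(2, EAF)`: an exposure sample in which the quantitative
#' exposure is the genetic score plus normal noise scaled so the
#' variants explain `target_r2` of unit total variance, and an outcome
#' case-control sample in which disease is Bernoulli through a
#' logistic model with log-odds `theta` per exposure SD plus optional
#' per-variant direct (pleiotropic) effects.  Per-variant summary
#' statistics are computed by least squares (exposure) and logistic
#' regression (outcome) and emitted as GWAS tables in the
#' [read_gwas_table()] layout, pre-aligned on a common effect allele.
#'
#' @param params A [gwas_sim_params()] list.
#' @return A list with `exposure` and `outcome` summary tables and a
#'   `truth` record (`theta`, true per-allele effects, target and
#'   realized exposure R-squared, realized case/control counts).
#' @export
simulate_gwas_summary <- function(params = gwas_sim_params()) {
  stopifnot(inherits(params, "gwas_sim_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  k <- params$k
  eaf <- params$eaf

  beta_true <- params$beta_pattern
  if (!is.null(params$target_r2)) {
    if (params$target_r2 <= 0 || params$target_r2 >= 1) {
      stop("target_r2 must lie in (0, 1)", call. = FALSE)
    }
    var_g <- sum(2 * eaf * (1 - eaf) * beta_true^2)
    if (var_g == 0) {
      stop("target R2 unattainable: all true effects are zero",
           call. = FALSE)
    }
    beta_true <- beta_true * sqrt(params$target_r2 / var_g)
    noise_sd <- sqrt(1 - params$target_r2)
  } else {
    noise_sd <- 1
  }

  snp_ids <- sprintf("sim%02d", seq_len(k))
  make_geno <- function(n) {
    matrix(stats::rbinom(n * k, 2L, rep(eaf, each = n)), nrow = n)
  }

  # exposure sample
  n1 <- params$n_exposure
  g1 <- make_geno(n1)
  x1 <- drop(g1 %*% beta_true) + stats::rnorm(n1, 0, noise_sd)
  exp_stats <- t(vapply(seq_len(k),
                        function(j) per_snp_ols(g1[, j], x1),
                        numeric(2)))

  # outcome sample (independent of the exposure sample)
  n2 <- params$n_cases + params$n_controls
  phi <- params$n_cases / n2
  g2 <- make_geno(n2)
  x2 <- drop(g2 %*% beta_true) + stats::rnorm(n2, 0, noise_sd)
  eta <- stats::qlogis(phi) + params$theta * x2 +
    drop(g2 %*% params$pleiotropy)
  y <- stats::rbinom(n2, 1L, stats::plogis(eta))
  out_stats <- t(vapply(seq_len(k),
                        function(j) per_snp_logistic(g2[, j], y),
                        numeric(2)))

  gwas_table <- function(stats_mat, eaf_hat, n, trait) {
    z <- stats_mat[, "beta"] / stats_mat[, "se"]
    data.frame(snp = snp_ids, chr = "1", pos = seq_len(k) * 100000,
               effect_allele = "A", other_allele = "G",
               eaf = eaf_hat,
               beta = stats_mat[, "beta"], se = stats_mat[, "se"],
               pval = 2 * stats::pnorm(-abs(z)), n = n,
               trait = trait, stringsAsFactors = FALSE)
  }

  list(
    exposure = gwas_table(exp_stats, colMeans(g1) / 2, n1,
                          "simulated exposure"),
    outcome = gwas_table(out_stats, colMeans(g2) / 2, n2,
                         "simulated outcome"),
    truth = list(theta = params$theta,
                 beta_true = stats::setNames(beta_true, snp_ids),
                 pleiotropy = params$pleiotropy,
                 r2_target = params$target_r2,
                 r2_realized = stats::var(drop(g1 %*% beta_true)) /
                   stats::var(x1),
                 n_cases_realized = sum(y),
                 n_controls_realized = sum(1 - y))
  )
}
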