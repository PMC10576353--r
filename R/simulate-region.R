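#' Parameters for the LD-region simulator
#'
#' Defaults produce a 50-variant region with first-order
#' autoregressive linkage disequilibrium (latent correlation
#' `rho_ld^|i-j|`), two quantitative traits of 10,000 subjects each,
#' and strong per-allele effects at the designated causal variants.
#'
#' @param ... Named overrides: `m` (variant count), `rho_ld`, `eaf`
#'   (scalar or per-variant; default 0.5), `config` (`"shared"`,
#'   `"distinct"`, or `"none"`), `causal1`, `causal2` (variant indices;
#'   for `"shared"` both default to the middle variant, for
#'   `"distinct"` they default to the first and third quartile
#'   positions), `effect1`, `effect2` (per-allele effects),
#'   `n1`, `n2` (per-trait sample sizes), `trait1_type`, `trait2_type`
#'   (`"quantitative"` or `"binary"`; binary traits use the effect on
#'   the log-odds scale with 10% baseline prevalence), `seed`.
#' @return A list of class `region_sim_params`.
#' @export
region_sim_params <- function(...) {
  p <- list(
    m = 50L,
    rho_ld = 0.8,
    eaf = 0.5,
    config = "shared",
    causal1 = NULL,
    causal2 = NULL,
    effect1 = 0.15,
    effect2 = 0.15,
    n1 = 10000L,
    n2 = 10000L,
    trait1_type = "quantitative",
    trait2_type = "quantitative",
    seed = NULL
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(p))
  if (length(unknown) > 0L) {
    stop("unknown region simulation parameter(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  p[names(over)] <- over
  if (abs(p$rho_ld) >= 1) stop("|rho_ld| must be < 1", call. = FALSE)
  p$config <- match.arg(p$config, c("shared", "distinct", "none"))
  if (length(p$eaf) == 1L) p$eaf <- rep(p$eaf, p$m)
  if (length(p$eaf) != p$m) {
    stop("eaf must have length 1 or m", call. = FALSE)
  }
  if (p$config == "shared") {
    if (is.null(p$causal1)) p$causal1 <- as.integer(ceiling(p$m / 2))
    p$causal2 <- p$causal1
  } else if (p$config == "distinct") {
    if (is.null(p$causal1)) p$causal1 <- max(1L, as.integer(p$m %/% 4))
    if (is.null(p$causal2)) p$causal2 <- min(p$m, as.integer(3 * p$m %/% 4))
    if (p$causal1 == p$causal2) {
      stop("distinct configuration requires different causal indices",
           call. = FALSE)
    }
  } else {
    p$causal1 <- p$causal2 <- NA_integer_
  }
  if (!is.na(p$causal1) && (p$causal1 > p$m || p$causal2 > p$m)) {
    stop("causal indices must not exceed m", call. = FALSE)
  }
  structure(p, class = "region_sim_params")
}

# n x m dosage matrix: two haplotypes, each a thresholded AR(1)
# latent Gaussian.  The latent lag-1 correlation is sin(pi*rho/2)
# (the tetrachoric inversion, exact at EAF 0.5) so that the realized
# dosage correlation at lag 1 approximates rho.
ar1_dosages <- function(n, m, rho, eaf) {
  rho <- sin(pi * rho / 2)
  hap <- function() {
    z <- matrix(stats::rnorm(n * m), nrow = n)
    if (m > 1L) {
      for (j in 2:m) {
        z[, j] <- rho * z[, j - 1] + sqrt(1 - rho^2) * z[, j]
      }
    }
    z
  }
  thr <- stats::qnorm(1 - eaf)
  (sweep(hap(), 2, thr, `>`) + 0) + (sweep(hap(), 2, thr, `>`) + 0)
}

marginal_quantitative <- function(g, y) {
  n <- length(y)
  gc <- sweep(g, 2, colMeans(g))
  yc <- y - mean(y)
  sxx <- colSums(gc^2)
  sxy <- colSums(gc * yc)
  bhat <- sxy / sxx
  sse <- sum(yc^2) - bhat^2 * sxx
  se <- sqrt(sse / (n - 2) / sxx)
  data.frame(beta = bhat, se = se)
}

marginal_binary <- function(g, y) {
  stats_mat <- t(vapply(seq_len(ncol(g)),
                        function(j) per_snp_logistic(g[, j], y),
                        numeric(2)))
  data.frame(beta = stats_mat[, "beta"], se = stats_mat[, "se"])
}

#' Simulate regional two-trait summary statistics under LD
#'
#' Generates genotype dosages for a region with AR(1) linkage
#' disequilibrium, builds two traits from the designated causal
#' variants (one shared variant, two distinct variants, or no causal
#' variant at all), and emits per-variant marginal summary statistics
#' for both traits — the input expected by [coloc_enumerate()].
#'
#' @param params A [region_sim_params()] list.
#' @return A list with per-trait tables `trait1` and `trait2`
#'   (`variant_id`, `beta`, `se`, `n`), a ready [regional_dataset()]
#'   as `region`, and a `truth` record (configuration, causal indices,
#'   empirical lag-1 genotype correlation).
#' @export
simulate_ld_region <- function(params = region_sim_params()) {
  stopifnot(inherits(params, "region_sim_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  m <- params$m
  ids <- sprintf("var%03d", seq_len(m))

  one_trait <- function(n, causal, effect, type) {
    g <- ar1_dosages(n, m, params$rho_ld, params$eaf)
    signal <- if (is.na(causal)) 0 else effect * g[, causal]
    if (type == "quantitative") {
      y <- signal + stats::rnorm(n)
      stats_df <- marginal_quantitative(g, y)
    } else if (type == "binary") {
      y <- stats::rbinom(n, 1L, stats::plogis(stats::qlogis(0.1) + signal))
      stats_df <- marginal_binary(g, y)
    } else {
      stop("trait type must be 'quantitative' or 'binary'", call. = FALSE)
    }
    lag1 <- if (m > 1L) {
      mean(vapply(seq_len(m - 1L),
                  function(j) stats::cor(g[, j], g[, j + 1L]),
                  numeric(1)))
    } else NA_real_
    list(stats = stats_df, lag1 = lag1)
  }

  t1 <- one_trait(params$n1, params$causal1, params$effect1,
                  params$trait1_type)
  t2 <- one_trait(params$n2, params$causal2, params$effect2,
                  params$trait2_type)

  region <- regional_dataset(ids,
                             beta1 = t1$stats$beta, se1 = t1$stats$se,
                             beta2 = t2$stats$beta, se2 = t2$stats$se,
                             trait1_type = params$trait1_type,
                             trait2_type = params$trait2_type)
  list(
    trait1 = cbind(data.frame(variant_id = ids), t1$stats,
                   n = params$n1),
    trait2 = cbind(data.frame(variant_id = ids), t2$stats,
                   n = params$n2),
    region = region,
    truth = list(config = params$config,
                 causal1 = params$causal1, causal2 = params$causal2,
                 rho_ld = params$rho_ld,
                 lag1_genotype_cor = mean(c(t1$lag1, t2$lag1),
                                          na.rm = TRUE))
  )
}
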