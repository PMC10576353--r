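#' Wakefield approximate Bayes factor (log scale)
#'
#' Closed-form approximate Bayes factor for a single association from
#' its estimate, standard error, and a normal prior on the true effect
#' with variance `w`.  With `V = se^2`, `z = beta/se` and shrinkage
#' `r = w / (w + V)`, the log Bayes factor in favour of a non-zero
#' effect is `0.5 log(1 - r) + z^2 r / 2`.  Vectorized over variants;
#' all downstream arithmetic stays on the log scale so no per-variant
#' Bayes factor can overflow.
#'
#' @param beta Effect estimate(s).
#' @param se Positive standard error(s).
#' @param w Prior effect variance (> 0), scalar or per-variant.
#' @return Log Bayes factor(s).
#' @export
log_abf <- function(beta, se, w) {
  if (any(se <= 0)) stop("se must be positive", call. = FALSE)
  if (any(w <= 0)) stop("prior variance w must be positive", call. = FALSE)
  v <- se^2
  z <- beta / se
  r <- w / (w + v)
  0.5 * log1p(-r) + z^2 * r / 2
}

default_prior_sd <- function(trait_type) {
  switch(trait_type, quantitative = 0.2, binary = 0.15,
         stop("trait type must be 'quantitative' or 'binary'",
              call. = FALSE))
}

#' Assemble a two-trait regional dataset for colocalization
#'
#' Aligns per-variant summary statistics for two traits over one
#' genomic region.  Prior effect standard deviations default to the
#' established enumeration-colocalization convention: 0.2 (trait-SD
#' units) for a quantitative trait and 0.15 (log-odds) for a binary
#' trait.
#'
#' @param variant_ids Variant labels, identical ordering for both
#'   traits.
#' @param beta1,se1 Trait-1 effects and standard errors.
#' @param beta2,se2 Trait-2 effects and standard errors.
#' @param trait1_type,trait2_type `"quantitative"` or `"binary"`.
#' @param w1,w2 Optional prior effect variances (squared effect units);
#'   default from the trait types.
#' @return An object of class `regional_dataset`.
#' @export
regional_dataset <- function(variant_ids, beta1, se1, beta2, se2,
                             trait1_type = "quantitative",
                             trait2_type = "binary",
                             w1 = NULL, w2 = NULL) {
  m <- length(variant_ids)
  lens <- c(length(beta1), length(se1), length(beta2), length(se2))
  if (m < 1L || any(lens != m)) {
    stop("all vectors must share the same length >= 1", call. = FALSE)
  }
  if (any(se1 <= 0) || any(se2 <= 0)) {
    stop("all standard errors must be positive", call. = FALSE)
  }
  if (is.null(w1)) w1 <- default_prior_sd(trait1_type)^2
  if (is.null(w2)) w2 <- default_prior_sd(trait2_type)^2
  structure(list(variant_ids = as.character(variant_ids),
                 beta1 = beta1, se1 = se1, beta2 = beta2, se2 = se2,
                 trait1_type = trait1_type, trait2_type = trait2_type,
                 w1 = w1, w2 = w2),
            class = "regional_dataset")
}

log_sum_exp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b
log_diff_exp <- function(a, b) {
  if (b == -Inf) return(a)
  if (a < b) stop("log_diff_exp requires a >= b", call. = FALSE)
  if (a == b) return(-Inf)
  a + log1p(-exp(b - a))
}

#' Enumeration colocalization of two traits over a region
#'
#' Bayesian enumeration over the five single-causal-variant hypotheses
#' for two traits in one region: no association (H0), association with
#' trait 1 only (H1), trait 2 only (H2), both traits through distinct
#' variants (H3), and both traits through one shared variant (H4).
#' Per-variant evidence comes from Wakefield approximate Bayes factors
#' ([log_abf()]); the unnormalized hypothesis weights are
#' `H0 = 1`, `H1 = p1 sum(B1)`, `H2 = p2 sum(B2)`,
#' `H3 = p1 p2 sum_{i != j} B1_i B2_j`, `H4 = p12 sum(B1_i B2_i)`,
#' and posterior probabilities are the normalized weights.  All sums
#' are evaluated in log space with log-sum-exp.
#'
#' The default priors follow the standard convention:
#' `p1 = p2 = 1e-4` per variant, and the colocalization prior `p12`
#' either `1e-5` ("standard") or `1e-4` ("relaxed").
#'
#' @param region A [regional_dataset()].
#' @param p1,p2 Per-variant prior probabilities that a variant is
#'   causal for trait 1 (resp. 2) only.
#' @param p12 Per-variant prior probability that a variant is causal
#'   for both traits.
#' @return An object of class `coloc_result` with posterior
#'   probabilities `pp0`..`pp4` (summing to one), the priors, and the
#'   per-variant log Bayes factors `log_abf1`, `log_abf2`.
#' @export
coloc_enumerate <- function(region, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  if (!inherits(region, "regional_dataset")) {
    stop("expected a regional_dataset", call. = FALSE)
  }
  if (p1 <= 0 || p2 <= 0 || p12 <= 0) {
    stop("priors must be positive", call. = FALSE)
  }
  m <- length(region$variant_ids)
  if (m * (p1 + p2 + p12) > 1) {
    warning("priors are large relative to the variant count; ",
            "posteriors may be prior-dominated", call. = FALSE)
  }
  l1 <- log_abf(region$beta1, region$se1, region$w1)
  l2 <- log_abf(region$beta2, region$se2, region$w2)

  ls1 <- log_sum_exp(l1)                 # log sum B1
  ls2 <- log_sum_exp(l2)                 # log sum B2
  ls12 <- log_sum_exp(l1 + l2)           # log sum B1*B2 (same variant)

  lh <- c(h0 = 0,
          h1 = log(p1) + ls1,
          h2 = log(p2) + ls2,
          h3 = if (m > 1L) {
            log(p1) + log(p2) + log_diff_exp(ls1 + ls2, ls12)
          } else -Inf,
          h4 = log(p12) + ls12)
  pp <- exp(lh - log_sum_exp(lh))
  structure(list(pp0 = pp[["h0"]], pp1 = pp[["h1"]], pp2 = pp[["h2"]],
                 pp3 = pp[["h3"]], pp4 = pp[["h4"]],
                 p1 = p1, p2 = p2, p12 = p12,
                 log_abf1 = stats::setNames(l1, region$variant_ids),
                 log_abf2 = stats::setNames(l2, region$variant_ids)),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("Enumeration colocalization (%d variants; p1 = %g, p2 = %g, p12 = %g)\n",
              length(x$log_abf1), x$p1, x$p2, x$p12))
  pp <- c(x$pp0, x$pp1, x$pp2, x$pp3, x$pp4)
  names(pp) <- c("PP0", "PP1", "PP2", "PP3", "PP4")
  print(round(pp, 4))
  invisible(x)
}
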