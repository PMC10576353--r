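# Independent oracles and small fixture builders shared across tests.

# instrument set straight from coefficient vectors
make_set <- function(bx, by, sy, sx = rep(0.01, length(bx)),
                     correlation = NULL) {
  instrument_set(data.frame(
    snp = sprintf("rs%03d", seq_along(bx)),
    beta_exposure = bx, se_exposure = sx,
    beta_outcome = by, se_outcome = sy,
    eaf_exposure = rep(0.3, length(bx)),
    flipped = FALSE), correlation = correlation)
}

# the published three-instrument panel, as plain vectors
tab4 <- list(bx = c(0.11, 0.26, -0.59), sx = c(0.01, 0.04, 0.10),
             by = c(-0.01, 0.05, -0.07), sy = c(0.01, 0.03, 0.08),
             eaf = c(0.13, 0.97, 0.01), n = 20436, k = 3)

# no-intercept logistic regression on case-minus-control differences:
# the closed-form equivalent of the 1:1 conditional likelihood
pair_difference_logit <- function(data, covariates, set = "set_id",
                                  case = "is_case") {
  sp <- split(data, data[[set]])
  D <- t(vapply(sp, function(d) {
    ca <- d[as.logical(d[[case]]), covariates, drop = FALSE]
    co <- d[!as.logical(d[[case]]), covariates, drop = FALSE]
    as.numeric(ca[1, ]) - as.numeric(co[1, ])
  }, numeric(length(covariates))))
  if (length(covariates) == 1L) D <- matrix(D, ncol = 1)
  colnames(D) <- covariates
  fit <- suppressWarnings(
    glm(rep(1, nrow(D)) ~ 0 + D, family = binomial()))
  coefs <- coef(fit)
  names(coefs) <- covariates
  list(coefficients = coefs, loglik = as.numeric(logLik(fit)))
}

# brute-force enumeration over all (c1, c2) causal configurations,
# plain (non-log) arithmetic; reference for coloc_enumerate at small m
coloc_brute_force <- function(region, p1, p2, p12) {
  b1 <- exp(log_abf(region$beta1, region$se1, region$w1))
  b2 <- exp(log_abf(region$beta2, region$se2, region$w2))
  m <- length(b1)
  w <- c(h0 = 0, h1 = 0, h2 = 0, h3 = 0, h4 = 0)
  for (c1 in 0:m) {
    for (c2 in 0:m) {
      lik <- (if (c1 > 0) b1[c1] else 1) * (if (c2 > 0) b2[c2] else 1)
      prior <- if (c1 == 0 && c2 == 0) 1
      else if (c2 == 0) p1
      else if (c1 == 0) p2
      else if (c1 == c2) p12
      else p1 * p2
      h <- if (c1 == 0 && c2 == 0) "h0"
      else if (c2 == 0) "h1"
      else if (c1 == 0) "h2"
      else if (c1 == c2) "h4"
      else "h3"
      w[h] <- w[h] + prior * lik
    }
  }
  w / sum(w)
}

# random 1:1 matched data with a known linear effect
random_pairs <- function(n_sets, beta, n_cov = 1, seed) {
  set.seed(seed)
  rows <- lapply(seq_len(n_sets), function(s) {
    x <- matrix(rnorm(2 * n_cov), nrow = 2)
    eta <- drop(x %*% rep(beta, n_cov))
    p_case1 <- exp(eta[1]) / (exp(eta[1]) + exp(eta[2]))
    first_is_case <- runif(1) < p_case1
    d <- as.data.frame(x)
    names(d) <- paste0("x", seq_len(n_cov))
    d$set_id <- s
    d$is_case <- if (first_is_case) c(TRUE, FALSE) else c(FALSE, TRUE)
    d
  })
  do.call(rbind, rows)
}
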