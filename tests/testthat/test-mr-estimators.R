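test_that("Wald ratio matches direct arithmetic on the cis instrument", {
  res <- mr_wald(fabp4_instruments(), snp = "rs77878271")
  expect_equal(res$beta_causal, 0.05 / 0.26, tolerance = 1e-12)
  expect_equal(res$se, 0.03 / 0.26, tolerance = 1e-12)
  expect_equal(res$or_point, exp(res$beta_causal))
  expect_lt(res$ci_low, res$or_point)
  expect_gt(res$ci_high, res$or_point)

  # null numerator and identity instrument
  expect_equal(mr_wald(make_set(0.26, 0, 0.03))$or_point, 1)
  ident <- mr_wald(make_set(1, 0.2, 0.07))
  expect_equal(ident$beta_causal, 0.2)
  expect_equal(ident$se, 0.07)
  expect_error(mr_wald(make_set(0, 0.1, 0.03)), "zero")
})

test_that("fixed-effects IVW equals the weighted-average closed form", {
  expected <- with(tab4, sum(bx * by / sy^2) / sum(bx^2 / sy^2))
  res <- mr_ivw(fabp4_instruments())
  expect_equal(res$beta_causal, expected, tolerance = 1e-12)
  expect_equal(res$se, with(tab4, 1 / sqrt(sum(bx^2 / sy^2))),
               tolerance = 1e-12)
  # frozen values from the closed form
  expect_equal(res$beta_causal, 0.03951098, tolerance = 1e-6)
  expect_equal(res$se, 0.06318218, tolerance = 1e-6)

  # single instrument reduces to the Wald ratio
  s1 <- make_set(0.26, 0.05, 0.03)
  expect_equal(mr_ivw(s1)$beta_causal, mr_wald(s1)$beta_causal)
  expect_equal(mr_ivw(s1)$se, mr_wald(s1)$se)

  # duplicating an instrument halves the variance
  s2 <- make_set(c(0.26, 0.26), c(0.05, 0.05), c(0.03, 0.03))
  expect_equal(mr_ivw(s2)$beta_causal, mr_ivw(s1)$beta_causal)
  expect_equal(mr_ivw(s2)$se, mr_ivw(s1)$se / sqrt(2), tolerance = 1e-12)
})

test_that("IVW equals the precision-weighted mean of Wald ratios", {
  set.seed(42)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    bx <- rnorm(k, 0.3, 0.2); bx[abs(bx) < 0.05] <- 0.1
    by <- rnorm(k, 0.05, 0.05)
    sy <- runif(k, 0.01, 0.1)
    s <- make_set(bx, by, sy)
    w <- (bx / sy)^2
    expect_equal(mr_ivw(s)$beta_causal, sum(w * (by / bx)) / sum(w),
                 tolerance = 1e-10)
  }
})

test_that("correlated-instrument GLS reduces to IVW under identity and handles rank-1 duplication", {
  set.seed(7)
  for (i in 1:25) {
    k <- sample(2:5, 1)
    s <- make_set(rnorm(k, 0.3, 0.1), rnorm(k, 0.05, 0.03),
                  runif(k, 0.01, 0.1), correlation = diag(k))
    a <- mr_ivw(s); b <- mr_ivw_correlated(s)
    expect_equal(b$beta_causal, a$beta_causal, tolerance = 1e-12)
    expect_equal(b$se, a$se, tolerance = 1e-12)
  }

  # duplicated instrument with correlation ~1 adds no precision
  eps <- 1e-10
  rho <- matrix(c(1, 1 - eps, 1 - eps, 1), 2)
  dup <- make_set(c(0.26, 0.26), c(0.05, 0.05), c(0.03, 0.03),
                  correlation = rho)
  single <- mr_wald(make_set(0.26, 0.05, 0.03))
  res <- mr_ivw_correlated(dup)
  expect_equal(res$beta_causal, single$beta_causal, tolerance = 1e-6)
  expect_equal(res$se, single$se, tolerance = 1e-4)

  # explicit 2x2 matrix-inverse oracle
  two <- make_set(c(0.2, 0.1), c(0.02, 0.005), c(0.01, 0.01),
                  correlation = matrix(c(1, 0.3, 0.3, 1), 2))
  res2 <- mr_ivw_correlated(two)
  omega <- diag(c(0.01, 0.01)) %*% matrix(c(1, 0.3, 0.3, 1), 2) %*%
    diag(c(0.01, 0.01))
  oi <- solve(omega)
  x <- c(0.2, 0.1); y <- c(0.02, 0.005)
  expect_equal(res2$beta_causal,
               drop(solve(t(x) %*% oi %*% x) %*% t(x) %*% oi %*% y),
               tolerance = 1e-12)
  expect_equal(res2$beta_causal, 0.09473684, tolerance = 1e-7)
  expect_equal(res2$se, 0.04893605, tolerance = 1e-7)

  expect_error(mr_ivw_correlated(make_set(0.2, 0.02, 0.01)),
               "no correlation")
})

test_that("MR-Egger matches a weighted-regression oracle on the instrument panel", {
  res <- mr_egger(fabp4_instruments())
  # oracle: weighted lm on the orientation-flipped coefficients
  bx <- c(0.11, 0.26, 0.59); by <- c(-0.01, 0.05, 0.07)
  w <- 1 / c(0.01, 0.03, 0.08)^2
  fit <- lm(by ~ bx, weights = w)
  expect_equal(res$beta_causal, unname(coef(fit)[2]), tolerance = 1e-10)
  expect_equal(res$egger_intercept, unname(coef(fit)[1]),
               tolerance = 1e-10)
  expect_equal(res$beta_causal, 0.256232, tolerance = 1e-5)
  expect_equal(res$egger_intercept, -0.0366551, tolerance = 1e-5)
  expect_equal(res$se, 0.133850, tolerance = 1e-5)

  # exact linear relation recovers slope and intercept with no residual
  bx2 <- c(0.1, 0.2, 0.3, 0.4)
  exact <- mr_egger(make_set(bx2, 0.05 + 0.3 * bx2, rep(0.02, 4)))
  expect_equal(exact$beta_causal, 0.3, tolerance = 1e-10)
  expect_equal(exact$egger_intercept, 0.05, tolerance = 1e-10)

  expect_error(mr_egger(make_set(c(0.1, 0.2), c(0.01, 0.02),
                                 c(0.01, 0.01))), "at least 3")

  # t reference is wider than normal for the intercept test
  res_t <- mr_egger(fabp4_instruments(), p_reference = "t")
  expect_gt(res_t$pleiotropy_p, res$pleiotropy_p)
})

test_that("Egger with the intercept constrained to zero reproduces IVW", {
  set.seed(99)
  for (i in 1:10) {
    s <- make_set(rnorm(4, 0.3, 0.1), rnorm(4, 0.05, 0.03),
                  runif(4, 0.01, 0.1))
    a <- mr_ivw(s)
    b <- mr_egger(s, intercept = FALSE, se_type = "fixed")
    expect_equal(b$beta_causal, a$beta_causal, tolerance = 1e-10)
    expect_equal(b$se, a$se, tolerance = 1e-10)
  }
})

test_that("estimators are sign-equivariant in the outcome", {
  set.seed(5)
  s <- make_set(rnorm(4, 0.3, 0.1), rnorm(4, 0.05, 0.03),
                runif(4, 0.01, 0.1))
  neg <- make_set(s$instruments$beta_exposure,
                  -s$instruments$beta_outcome,
                  s$instruments$se_outcome)
  expect_equal(mr_ivw(neg)$beta_causal, -mr_ivw(s)$beta_causal)
  expect_equal(mr_ivw(neg)$se, mr_ivw(s)$se)
  expect_equal(mr_egger(neg)$beta_causal, -mr_egger(s)$beta_causal)
})

test_that("heterogeneity Q matches hand arithmetic and handles stratum contrasts", {
  h <- heterogeneity_q(c(0, 2), c(1, 1))
  expect_equal(h$q_statistic, 2)
  expect_equal(h$df, 1L)
  expect_equal(h$p_value, 0.1573, tolerance = 1e-4)
  expect_equal(h$beta_pooled, 1)

  same <- heterogeneity_q(c(0.3, 0.3, 0.3), c(0.1, 0.2, 0.3))
  expect_equal(same$q_statistic, 0)
  expect_equal(same$p_value, 1)

  # sex-stratified per-SD estimates reconstructed from printed CIs
  men <- log_or_from_ci(1.07, 0.92, 1.23)
  women <- log_or_from_ci(1.12, 1.00, 1.26)
  hs <- heterogeneity_q(c(men$beta, women$beta), c(men$se, women$se))
  expect_equal(hs$q_statistic, 0.233, tolerance = 0.01)
  expect_equal(hs$p_value, 0.63, tolerance = 0.01)

  expect_error(heterogeneity_q(0.1, 0.1), "at least 2")
  expect_error(heterogeneity_q(c(0, 1), c(1, -1)), "positive")
})
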