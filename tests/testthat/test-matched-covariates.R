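test_that("ABSI follows its defining formula and scaling law", {
  expect_equal(absi(89, 75, 167),
               890 * 75^(-2 / 3) * 1.67^(5 / 6), tolerance = 1e-12)
  expect_equal(absi(100, 100, 180), 75.75, tolerance = 0.01)
  # 8-fold weight divides the index by 4
  expect_equal(absi(89, 75 * 8, 167), absi(89, 75, 167) / 4,
               tolerance = 1e-12)
  expect_error(absi(-1, 75, 167), "positive")
})

test_that("waist residuals match an OLS oracle and impute by sex-specific medians", {
  d <- data.frame(bmi = c(20, 25, 30), height = c(170, 170, 170),
                  waist = c(70, 80, 96), sex = "male")
  # height is constant here, so include only bmi to keep full rank
  r <- covariate_residuals(d, predictors = "bmi")
  oracle <- resid(lm(waist ~ bmi, data = d))
  expect_equal(r$residual, unname(oracle), tolerance = 1e-10)
  expect_equal(r$residual, c(1, -2, 1), tolerance = 1e-10)

  # exact linear response leaves zero residuals
  d2 <- data.frame(bmi = rnorm(20, 26, 3), height = rnorm(20, 170, 8),
                   sex = rep(c("male", "female"), 10))
  d2$waist <- 10 + 2 * d2$bmi + 0.3 * d2$height
  expect_equal(covariate_residuals(d2)$residual, rep(0, 20),
               tolerance = 1e-8)

  # missing waist receives the sex-specific median residual
  set.seed(31)
  d3 <- data.frame(bmi = rnorm(40, 26, 3), height = rnorm(40, 170, 8),
                   sex = rep(c("male", "female"), each = 20))
  d3$waist <- -30 + 2.5 * d3$bmi + 0.3 * d3$height + rnorm(40, 0, 4)
  d3$waist[c(1, 21)] <- NA
  r3 <- covariate_residuals(d3)
  expect_true(all(r3$imputed[c(1, 21)]))
  med_m <- median(r3$residual[d3$sex == "male" & !r3$imputed])
  med_f <- median(r3$residual[d3$sex == "female" & !r3$imputed])
  expect_equal(r3$residual[1], med_m)
  expect_equal(r3$residual[21], med_f)
  r3cc <- covariate_residuals(d3, impute = FALSE)
  expect_true(all(is.na(r3cc$residual[c(1, 21)])))

  expect_error(covariate_residuals(
    data.frame(bmi = rep(1, 5), height = rep(2, 5),
               waist = rnorm(5), sex = "male")), "degenerate")
})

test_that("quintile cut-offs use control distributions per sex", {
  d <- data.frame(biomarker = c(1:10, 10.0, 0.5),
                  sex = "male",
                  is_case = c(rep(FALSE, 10), TRUE, TRUE))
  q <- assign_quintiles(d)
  expect_equal(unname(q$cutoffs$male),
               unname(quantile(1:10, c(0.2, 0.4, 0.6, 0.8), type = 7)))
  # a case at the control maximum lands in the top quintile,
  # one below the control minimum in the bottom quintile
  expect_equal(q$assignment$quintile[11], 5L)
  expect_equal(q$assignment$quintile[12], 1L)
  expect_equal(q$control_sd, sd(1:10))
  # trend scores are the control medians of each quintile
  expect_equal(q$assignment$trend_score[1], 1.5)  # Q1 controls: 1, 2

  # degenerate distribution: everyone in the bottom category
  dd <- data.frame(biomarker = rep(7, 12), sex = "female",
                   is_case = rep(c(TRUE, FALSE), 6))
  qd <- assign_quintiles(dd)
  expect_true(all(qd$assignment$quintile == 1L))
})

test_that("quintile assignment is invariant to joint monotone transforms", {
  set.seed(41)
  d <- data.frame(biomarker = rlnorm(400, 2.5, 0.5),
                  sex = rep(c("male", "female"), 200),
                  is_case = rep(c(TRUE, FALSE), each = 200))
  q1 <- assign_quintiles(d)$assignment$quintile
  d2 <- d; d2$biomarker <- log(d$biomarker)
  expect_equal(assign_quintiles(d2)$assignment$quintile, q1)
  d3 <- d; d3$biomarker <- d$biomarker^3
  expect_equal(assign_quintiles(d3)$assignment$quintile, q1)
})

test_that("per-SD standardization divides by the control SD", {
  expect_equal(standardize_by_control_sd(8.9, 8.9), 1)
  expect_equal(standardize_by_control_sd(0, 8.9), 0)
  set.seed(51)
  d <- data.frame(biomarker = c(rnorm(200, 15, 8.9), 17.8),
                  sex = "male", is_case = c(rep(FALSE, 200), TRUE))
  scheme <- assign_quintiles(d)
  expect_equal(standardize_by_control_sd(17.8, scheme),
               17.8 / sd(d$biomarker[1:200]))
  expect_error(standardize_by_control_sd(1, 0), "positive")
})

test_that("set-level exclusion drops a case's whole set but controls individually", {
  d <- data.frame(set_id = rep(1:3, each = 2),
                  is_case = rep(c(TRUE, FALSE), 3),
                  diabetic = c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE))
  out <- exclude_matched_sets(d, d$diabetic)
  # set 1: case diabetic -> whole set gone;
  # set 2: control diabetic -> control gone, then the caseless set too
  expect_equal(unique(out$set_id), 3L)
  expect_equal(attr(out, "n_sets_dropped"), 2L)
})

test_that("Bonferroni helper uses the explicit family size", {
  expect_equal(bonferroni(0.002, 28), 0.056)
  expect_equal(bonferroni(0.2, 12), 1)
})

test_that("Spearman partial correlation equals a residualize-then-correlate oracle", {
  expect_equal(spearman_partial(1:10, (1:10)^2)$r, 1)
  expect_equal(spearman_partial(1:10, -(1:10)^3)$r, -1)

  set.seed(61)
  x <- rnorm(60); z <- rnorm(60); y <- 0.5 * x + 0.8 * z + rnorm(60)
  got <- spearman_partial(x, y, covariates = data.frame(z = z))
  rx <- resid(lm(rank(x) ~ z)); ry <- resid(lm(rank(y) ~ z))
  expect_equal(got$r, cor(rx, ry), tolerance = 1e-12)
  expect_equal(got$df, 60 - 3)
  tt <- got$r * sqrt(got$df / (1 - got$r^2))
  expect_equal(got$p_value, 2 * pt(-abs(tt), got$df), tolerance = 1e-12)

  # 5-point example with one covariate against the same oracle
  x5 <- c(3, 1, 4, 1.5, 9); y5 <- c(2, 7, 1, 8, 2); z5 <- c(1, 2, 3, 4, 5)
  got5 <- spearman_partial(x5, y5, covariates = data.frame(z = z5))
  ex5 <- cor(resid(lm(rank(x5) ~ z5)), resid(lm(rank(y5) ~ z5)))
  expect_equal(got5$r, ex5, tolerance = 1e-12)

  expect_error(spearman_partial(rep(1, 10), 1:10), "non-constant")
})
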