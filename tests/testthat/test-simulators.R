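test_that("cohort generation is seeded, sized, and hits its biomarker targets", {
  expect_equal(nrow(simulate_cohort(cohort_params(n_subjects = 0))), 0L)

  p <- cohort_params(n_subjects = 20000, seed = 101)
  co <- simulate_cohort(p)
  co2 <- simulate_cohort(p)
  expect_identical(co, co2)  # bit-reproducible under a fixed seed

  ctrl <- co[!co$event, ]
  expect_lt(abs(median(ctrl$biomarker[ctrl$sex == "male"]) - 12.1) / 12.1,
            0.05)
  expect_lt(abs(median(ctrl$biomarker[ctrl$sex == "female"]) - 18.3) / 18.3,
            0.05)
  # overall control SD near the study's 8.9 ng/mL scaling constant
  expect_lt(abs(sd(ctrl$biomarker) - 8.9), 1.5)
  expect_true(all(co$biomarker >= 0))
  expect_true(all(co$time <= p$horizon))
  expect_error(cohort_params(nonsense = 1), "unknown")
})

test_that("incidence-density matching respects strata and risk sets", {
  co <- simulate_cohort(cohort_params(n_subjects = 8000, seed = 103))
  m <- incidence_density_match(co, seed = 104)
  validate_matched_sets(m)
  sets <- split(m, m$set_id)
  for (s in sets[seq(1, length(sets), by = 25)]) {
    expect_equal(sum(s$is_case), 1L)
    expect_equal(length(unique(s$sex)), 1L)
    expect_equal(length(unique(s$center)), 1L)
    expect_lte(abs(diff(s$age)), 2)
    # control still at risk at the case's event time
    expect_gt(s$time[!s$is_case], s$case_time[1])
  }
  # a control can later become a case (incidence-density property)
  ctrl_ids <- m$subject_id[!m$is_case]
  case_ids <- m$subject_id[m$is_case]
  expect_gt(length(intersect(ctrl_ids, case_ids)), 0)

  # degenerate single-member strata: every set is dropped
  tiny <- co[1:6, ]
  tiny$center <- paste0("Z", 1:6)
  tiny$event <- TRUE
  tiny$time <- 1:6
  md <- incidence_density_match(tiny)
  expect_equal(nrow(md), 0L)
  expect_equal(attr(md, "n_sets_dropped"), 6L)
})

test_that("GWAS simulator calibrates R2 and gives null z-scores without effects", {
  g <- simulate_gwas_summary(gwas_sim_params(
    n_exposure = 20000, n_cases = 4000, n_controls = 4000, seed = 105))
  expect_lt(abs(g$truth$r2_realized - 0.01) / 0.01, 0.10)
  expect_identical(
    g$exposure$beta,
    simulate_gwas_summary(gwas_sim_params(
      n_exposure = 20000, n_cases = 4000, n_controls = 4000,
      seed = 105))$exposure$beta)

  # null exposure z-scores behave like standard normals
  zs <- unlist(lapply(1:40, function(i) {
    gg <- simulate_gwas_summary(gwas_sim_params(
      k = 5, eaf = rep(0.3, 5), beta_pattern = rep(0, 5),
      target_r2 = NULL, n_exposure = 1500, n_cases = 500,
      n_controls = 500, theta = 0, seed = 200 + i))
    gg$exposure$beta / gg$exposure$se
  }))
  ks <- ks.test(zs, "pnorm")
  expect_gt(ks$p.value, 0.01)
  expect_error(
    simulate_gwas_summary(gwas_sim_params(beta_pattern = c(0, 0, 0))),
    "unattainable")
})

test_that("LD-region simulator reproduces its target lag-1 correlation and truth record", {
  sim <- simulate_ld_region(region_sim_params(
    m = 30, n1 = 25000, n2 = 2000, seed = 106))
  expect_lt(abs(sim$truth$lag1_genotype_cor - 0.8), 0.05)
  expect_equal(sim$truth$causal1, sim$truth$causal2)  # shared

  dist <- simulate_ld_region(region_sim_params(
    m = 30, config = "distinct", n1 = 2000, n2 = 2000, seed = 107))
  expect_false(dist$truth$causal1 == dist$truth$causal2)
  expect_equal(length(dist$trait1$beta), 30L)
  expect_s3_class(dist$region, "regional_dataset")

  # binary trait path produces finite log-odds summaries
  bin <- simulate_ld_region(region_sim_params(
    m = 10, n1 = 2000, n2 = 4000, trait2_type = "binary", seed = 108))
  expect_true(all(is.finite(bin$trait2$beta)))
  expect_true(all(bin$trait2$se > 0))
})

test_that("null regions leave colocalization at the no-association hypothesis", {
  hits <- vapply(1:10, function(i) {
    sim <- simulate_ld_region(region_sim_params(
      m = 20, config = "none", n1 = 3000, n2 = 3000, seed = 300 + i))
    coloc_enumerate(sim$region)$pp0
  }, numeric(1))
  expect_gte(mean(hits > 0.9), 0.9)
})

test_that("end-to-end matching supports unbiased rate-ratio estimation", {
  # small-scale version of the design-validity check: the full-strength
  # replication lives in the acceptance suite
  ests <- ses <- numeric(8)
  for (i in 1:8) {
    p <- cohort_params(n_subjects = 8000, seed = 400 + i)
    co <- simulate_cohort(p)
    m <- incidence_density_match(co, seed = 500 + i)
    m <- m[!is.na(m$waist), ]
    m <- m[m$set_id %in% names(which(table(m$set_id) == 2)), ]
    m$bstd <- m$biomarker / p$sd_ref
    f <- clogit_fit(m, c("bstd", "waist"))
    ests[i] <- f$coefficients[["bstd"]]
    ses[i] <- sqrt(f$covariance["bstd", "bstd"])
  }
  expect_lt(abs(mean(ests) - 0.1), 2 * sd(ests) / sqrt(8) + 0.01)
})
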