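test_that("covariate generation is deterministic and matches target marginals", {
  cfg <- synthetic_config(n = 10000, seed = 5)
  a <- generate_covariates(cfg)
  b <- generate_covariates(cfg)
  expect_identical(a, b)

  expect_lt(abs(mean(a$donor_age) - 43.88), 0.5)
  expect_lt(abs(sd(a$donor_age) - 13.03), 0.5)
  expect_lt(abs(mean(a$recipient_years_dialysis) - 3.16), 0.15)
  expect_lt(abs(mean(a$donor_male) - 0.58), 0.02)
  expect_lt(abs(mean(a$hla_mismatch <= 1) - 0.12), 0.02)
  expect_lt(abs(mean(a$hla_mismatch %in% 2:3) - 0.54), 0.02)
  expect_true(all(a$recipient_max_pra >= 0 & a$recipient_max_pra <= 100))
  expect_true(all(a$hla_mismatch %in% 0:6))

  expect_error(synthetic_config(n = 0), "n must be")
})

test_that("simulated event fraction matches the closed form under an exponential baseline", {
  cfg <- synthetic_config(n = 20000, seed = 2,
                          true_log_hr = c(donor_age = 0), reference = c(),
                          baseline_shape = 1, baseline_scale = 0.1,
                          death_rate = 0, admin_censor = 5,
                          missing_rates = numeric(0))
  covar <- generate_covariates(cfg)
  X <- build_design_matrix(covar)
  out <- simulate_outcomes(X, cfg, seed = 99)
  expect_lt(abs(mean(out$outcome == "graft_failure") - (1 - exp(-0.5))), 0.01)
  expect_true(all(out$followup_time <= 5))
})

test_that("a strong positive effect induces positive covariate-event association", {
  cfg <- synthetic_config(n = 5000, seed = 3,
                          true_log_hr = c(donor_age = 0.08),
                          missing_rates = numeric(0))
  sim <- simulate_cohort(cfg, inject_missing = FALSE)
  tau <- cor(sim$complete$donor_age,
             as.numeric(sim$complete$outcome == "graft_failure"),
             method = "kendall")
  expect_gt(tau, 0)
})

test_that("null-effect Kaplan-Meier tracks the Weibull baseline", {
  cfg <- synthetic_config(n = 8000, seed = 4,
                          true_log_hr = c(donor_age = 0), reference = c(),
                          baseline_shape = 0.7, baseline_scale = 0.04,
                          death_rate = 0, admin_censor = 6,
                          missing_rates = numeric(0))
  covar <- generate_covariates(cfg)
  X <- build_design_matrix(covar)
  out <- simulate_outcomes(X, cfg, seed = 11)
  oc <- data.frame(time = out$followup_time,
                   event = as.integer(out$outcome == "graft_failure"))
  km <- kaplan_meier(oc)
  for (t in c(1, 3, 5)) {
    est <- curve_at(km, t)
    se <- curve_at(km, t, value = "std_err")
    expect_lt(abs(est - exp(-0.04 * t^0.7)), 2 * se + 1e-9)
  }
})

test_that("default study conditions give a plausible death-censored event fraction", {
  cfg <- synthetic_config(n = 822, seed = 1)
  for (s in c(1, 2)) {
    sim <- simulate_cohort(cfg, seed = s)
    evf <- mean(sim$complete$outcome == "graft_failure")
    expect_gte(evf, 0.10)
    expect_lte(evf, 0.25)
    expect_true(all(sim$complete$followup_time <= cfg$admin_censor))
  }
})

test_that("missingness injection hits target rates and is reproducible", {
  cfg <- synthetic_config(n = 822, seed = 6)
  sim <- simulate_cohort(cfg, inject_missing = FALSE)
  tab <- sim$complete

  masked <- inject_missingness(tab, c(donor_diabetes = 0.098), seed = 21)
  n_miss <- sum(is.na(masked$donor_diabetes))
  bound <- 3 * sqrt(822 * 0.098 * 0.902)
  expect_lt(abs(n_miss - 822 * 0.098), bound)

  expect_identical(inject_missingness(tab, c(donor_diabetes = 0.098),
                                      seed = 21), masked)
  expect_identical(inject_missingness(tab, c(donor_diabetes = 0)), tab)
  expect_error(inject_missingness(tab, c(outcome = 0.1)), "outcome")

  mar <- inject_missingness(tab, c(recipient_weight = 0.15),
                            mechanism = "MAR", seed = 8)
  expect_lt(abs(mean(is.na(mar$recipient_weight)) - 0.15), 0.04)
  ## MAR masking depends on the driver: era split shows a rate gradient
  early <- mar$transplant_year <= stats::median(mar$transplant_year)
  expect_lt(mean(is.na(mar$recipient_weight[early])),
            mean(is.na(mar$recipient_weight[!early])))
})

test_that("cohort simulation is deterministic end-to-end under one seed", {
  cfg <- synthetic_config(n = 100, seed = 9)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$design, b$design)
})
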