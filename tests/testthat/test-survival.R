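test_that("Kaplan-Meier reproduces the hand product-limit values", {
  oc <- data.frame(time = 1:4, event = c(1, 0, 1, 0))
  km <- kaplan_meier(oc)
  expect_equal(curve_at(km, 1), 3 / 4)
  expect_equal(curve_at(km, 3), 3 / 8)
  expect_true(all(km$lower <= km$surv & km$surv <= km$upper))

  allc <- data.frame(time = 1:5, event = rep(0, 5))
  expect_true(all(kaplan_meier(allc)$surv == 1))
  expect_error(kaplan_meier(data.frame(time = c(-1, 2), event = c(1, 0))),
               "> 0")
})

test_that("Kaplan-Meier equals the empirical survival function without censoring", {
  set.seed(1)
  t <- round(rexp(60, 1), 2)
  oc <- data.frame(time = t, event = rep(1L, 60))
  km <- kaplan_meier(oc)
  grid <- sort(unique(t))
  expect_equal(curve_at(km, grid), vapply(grid, function(g) mean(t > g),
                                          numeric(1)))
})

test_that("log-rank test matches hand computation and is label-invariant", {
  ## identical groups: no evidence
  oc <- data.frame(time = rep(c(1, 2, 3), 2), event = rep(c(1, 0, 1), 2))
  g <- rep(c("a", "b"), each = 3)
  res <- logrank_test(oc, g)
  expect_lt(res$chisq, 1e-10)
  expect_equal(res$p, 1, tolerance = 1e-6)

  ## 6-subject toy: hand-summed (O - E)^2 / V
  oc2 <- data.frame(time = c(1, 2, 3, 4, 5, 6),
                    event = c(1, 1, 1, 1, 0, 1))
  g2 <- c("a", "b", "a", "b", "a", "b")
  res2 <- logrank_test(oc2, g2)
  O <- E <- V <- 0
  for (k in which(oc2$event == 1)) {
    at_risk <- oc2$time >= oc2$time[k]
    n <- sum(at_risk); n_a <- sum(at_risk & g2 == "a")
    O <- O + (g2[k] == "a")
    E <- E + n_a / n
    if (n > 1) V <- V + n_a * (n - n_a) / n^2
  }
  expect_equal(res2$chisq, (O - E)^2 / V, tolerance = 1e-10)

  ## permuting labels leaves the statistic unchanged
  res3 <- logrank_test(oc2, c(b = "b", a = "a")[g2])
  expect_equal(res3$chisq, res2$chisq)
  expect_error(logrank_test(oc2, rep("a", 6)), "two groups")
})

test_that("log-rank equals the Cox score test for a binary group", {
  set.seed(4)
  n <- 80
  g <- rbinom(n, 1, 0.5)
  t <- rexp(n, exp(0.6 * g))
  t <- t + runif(n, 0, 1e-6)  # break ties
  oc <- data.frame(time = t, event = rbinom(n, 1, 0.8))
  lr <- logrank_test(oc, g)
  ord <- order(oc$time)
  parts <- graftnet:::cox_breslow_parts(matrix(g[ord], ncol = 1),
                                        oc$time[ord], oc$event[ord],
                                        rep(0, n), need_hessian = TRUE)
  score_test <- parts$score^2 / parts$info[1, 1]
  expect_equal(lr$chisq, unname(score_test), tolerance = 1e-6)
})

test_that("Newton Cox fit satisfies the score equation and a brute-force oracle", {
  inst <- make_surv_instance(60, 1, seed = 11, beta = 0.8)
  fit <- cox_fit(inst$X, inst$outcomes)
  expect_lt(max(abs(fit$score)), 1e-6)
  expect_true(all(diff(fit$loglik_trace) >= -1e-12))

  ## 1-D grid maximization of the independently coded partial likelihood
  grid <- seq(-3, 3, by = 1e-3)
  ll <- vapply(grid, function(b)
    naive_breslow_loglik(b, inst$X, inst$outcomes$time, inst$outcomes$event),
    numeric(1))
  expect_lt(abs(unname(coef(fit)) - grid[which.max(ll)]), 1e-3 + 1e-4)

  ## Wald pieces are internally consistent
  expect_equal(fit$hr, exp(coef(fit)), ignore_attr = TRUE)
  expect_equal(fit$ci_upper, exp(coef(fit) + 1.96 * fit$se),
               ignore_attr = TRUE)
})

test_that("Newton Cox fit agrees with the survival package on tied data", {
  sim <- simulate_cohort(synthetic_config(n = 400, seed = 2), seed = 2)
  X <- sim$design[, names(default_true_log_hr())]
  oc <- sim$outcomes
  oc$time <- round(oc$time, 1)  # induce ties
  oc$time[oc$time == 0] <- 0.05
  fit <- cox_fit(X, oc)
  ref <- survival::coxph(survival::Surv(oc$time, oc$event) ~ X,
                         ties = "breslow")
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-7)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(ref)))),
               tolerance = 1e-7)
})

test_that("degenerate designs are rejected with clear errors", {
  inst <- make_surv_instance(40, 3, seed = 5)
  X <- inst$X
  X[, 2] <- 1
  expect_error(cox_fit(X, inst$outcomes), "zero-variance")

  ## too few events for the number of coefficients draws a warning
  oc10 <- inst$outcomes[1:10, ]
  oc10$event <- c(1, 1, rep(0, 8))
  expect_warning(cox_fit(inst$X[1:10, ], oc10), "events")
})

test_that("concordance matches brute-force enumeration including ties", {
  ## worked tie-handling example
  oc <- data.frame(time = c(1, 2, 3), event = c(1, 1, 0))
  expect_equal(harrell_c(c(2, 2, 1), oc), 2.5 / 3)

  ## perfectly anti-ordered scores with all events
  oc2 <- data.frame(time = 1:6, event = rep(1, 6))
  expect_equal(harrell_c(6:1, oc2), 1)

  ## antisymmetry without score ties
  set.seed(9)
  sc <- rnorm(30)
  oc3 <- data.frame(time = rexp(30), event = rbinom(30, 1, 0.6))
  expect_equal(harrell_c(-sc, oc3), 1 - harrell_c(sc, oc3))

  for (s in 1:50) {
    set.seed(s)
    n <- sample(5:50, 1)
    time <- sample(1:8, n, replace = TRUE)     # many tied times
    event <- rbinom(n, 1, 0.6)
    score <- sample(1:5, n, replace = TRUE)    # many tied scores
    if (sum(event) == 0) event[1] <- 1
    oc4 <- data.frame(time = time, event = event)
    ours <- tryCatch(harrell_c(score, oc4), error = function(e) NA)
    if (is.na(ours)) next
    expect_identical(ours, brute_force_c(score, time, event))
  }

  expect_error(harrell_c(1, data.frame(time = 1, event = 1)), "comparable")
})

test_that("Breslow baseline reproduces Nelson-Aalen at beta = 0 and scales correctly", {
  oc <- data.frame(time = 1:4, event = c(1, 0, 1, 0))
  X <- matrix(rnorm(4), dimnames = list(NULL, "x"))
  null_fit <- list(coefficients = c(x = 0))
  bh <- breslow_baseline(null_fit, X, oc)
  expect_equal(curve_at(bh, 1, value = "hazard"), 1 / 4)
  expect_equal(curve_at(bh, 3, value = "hazard"), 3 / 4)
  expect_true(all(diff(bh$hazard) >= 0))

  ## doubling every centered risk halves each increment
  inst <- make_surv_instance(50, 2, seed = 3)
  fit <- cox_fit(inst$X, inst$outcomes)
  X1 <- cbind(inst$X, one = 1)
  f1 <- list(coefficients = c(fit$coefficients, one = 0))
  f2 <- list(coefficients = c(fit$coefficients, one = log(2)))
  h1 <- breslow_baseline(f1, X1, inst$outcomes)
  h2 <- breslow_baseline(f2, X1, inst$outcomes)
  expect_equal(h2$hazard, h1$hazard / 2, tolerance = 1e-12)

  expect_error(breslow_baseline(fit, inst$X, inst$outcomes,
                                reference = c(bogus = 1)), "reference")
})

test_that("profile survival prediction is monotone in risk", {
  sim <- simulate_cohort(synthetic_config(n = 600, seed = 6), seed = 6)
  X <- sim$design[, names(default_true_log_hr())]
  fit <- cox_fit(X, sim$outcomes)
  bh <- breslow_baseline(fit, X, sim$outcomes,
                         reference = c(donor_age = 40))
  ref_curve <- predict_survival(bh, fit)
  expect_equal(ref_curve$surv, exp(-bh$hazard))

  ## HLA mismatch 6 must sit below mismatch 0 when its coefficient is positive
  expect_gt(unname(coef(fit)["hla_mismatch"]), 0)
  c0 <- predict_survival(bh, fit, c(donor_age = 40, hla_mismatch = 0))
  c6 <- predict_survival(bh, fit, c(donor_age = 40, hla_mismatch = 6))
  expect_true(all(c6$surv <= c0$surv))
  expect_error(predict_survival(bh, fit, c(bogus = 2)), "profile")
})
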