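fit_default_model <- function(n = 500, seed = 1) {
  sim <- simulate_cohort(synthetic_config(n = n, seed = seed), seed = seed)
  X <- sim$design[, names(default_true_log_hr())]
  list(X = X, oc = sim$outcomes, fit = cox_fit(X, sim$outcomes),
       design = sim$design)
}

test_that("Schoenfeld residuals sum to zero at the optimum", {
  m <- fit_default_model(400, seed = 3)
  s <- schoenfeld_residuals(m$fit, m$X, m$oc)
  expect_lt(max(abs(colSums(s))), 1e-6)
  expect_equal(dim(s), c(sum(m$oc$event), ncol(m$X)))
  expect_equal(length(attr(s, "time")), sum(m$oc$event))

  ## scaled version: d * V %*% s + beta, row by row
  sc <- schoenfeld_residuals(m$fit, m$X, m$oc, scaled = TRUE)
  d <- sum(m$oc$event)
  manual <- d * (s %*% m$fit$vcov) +
    matrix(coef(m$fit), d, ncol(m$X), byrow = TRUE)
  expect_equal(unclass(sc), unclass(manual), ignore_attr = TRUE)
})

test_that("a single-event risk set gives the hand-computed residual", {
  X <- matrix(c(1, 2, 4), ncol = 1, dimnames = list(NULL, "x"))
  oc <- data.frame(time = c(1, 2, 3), event = c(1, 0, 0))
  fit <- list(coefficients = c(x = 0.5),
              vcov = matrix(1, dimnames = list("x", "x")))
  s <- schoenfeld_residuals(fit, X, oc)
  w <- exp(0.5 * c(1, 2, 4))
  expect_equal(unname(s[1, 1]), 1 - sum(w * c(1, 2, 4)) / sum(w))
})

test_that("the proportional-hazards test is invariant to affine rescaling", {
  m <- fit_default_model(400, seed = 5)
  pt1 <- ph_test(m$fit, m$X, m$oc)
  X2 <- m$X
  X2[, "donor_age"] <- (X2[, "donor_age"] - 40) / 10
  X2[, "hla_mismatch"] <- X2[, "hla_mismatch"] * 3
  fit2 <- cox_fit(X2, m$oc)
  pt2 <- ph_test(fit2, X2, m$oc)
  expect_lt(max(abs(pt1$table$chisq - pt2$table$chisq)), 1e-8)
  expect_lt(abs(pt1$global_chisq - pt2$global_chisq), 1e-8)
  expect_true(all(pt1$table$p >= 0 & pt1$table$p <= 1))
  expect_gte(pt1$global_chisq, 0)
  expect_identical(pt1$global_df, ncol(m$X))
})

test_that("the global test agrees with the survival package on identity time", {
  m <- fit_default_model(500, seed = 7)
  pt <- ph_test(m$fit, m$X, m$oc, transform = "identity")
  dd <- data.frame(time = m$oc$time, event = m$oc$event, m$X)
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(colnames(m$X), collapse = "+")))
  cz <- survival::cox.zph(survival::coxph(fml, data = dd, ties = "breslow"),
                          transform = "identity")
  expect_lt(abs(pt$global_p - cz$table["GLOBAL", "p"]), 0.05)
})

test_that("the test has power against a built-in time-varying effect", {
  set.seed(11)
  n <- 800
  x <- rbinom(n, 1, 0.5)
  ## piecewise hazard: the effect reverses over time
  t1 <- rexp(n, exp(1.5 * x))
  t2 <- 0.5 + rexp(n, exp(-1.5 * x))
  t <- ifelse(t1 < 0.5, t1, t2)
  oc <- data.frame(time = pmin(t, 3), event = as.integer(t <= 3))
  X <- matrix(x, ncol = 1, dimnames = list(NULL, "x"))
  fit <- cox_fit(X, oc)
  pt <- ph_test(fit, X, oc)
  expect_lt(pt$global_p, 0.01)

  ## degenerate transform: all events at one time
  occ <- data.frame(time = c(rep(1, 5), 2, 3), event = c(rep(1, 5), 0, 0))
  Xc <- matrix(rnorm(7), ncol = 1, dimnames = list(NULL, "x"))
  fitc <- list(coefficients = c(x = 0),
               vcov = matrix(1, dimnames = list("x", "x")))
  expect_error(ph_test(fitc, Xc, occ), "constant")
})

test_that("penalized-spline screen hits its target df and detects a hinge", {
  ## linear truth: nonlinear component quiet, linear component active
  sim <- simulate_cohort(synthetic_config(n = 1000, seed = 21,
    true_log_hr = c(donor_age = 0.04)), seed = 21)
  sp <- spline_nonlinearity_test(sim$design, sim$outcomes, "donor_age")
  expect_lt(abs(sp$df_used - 5), 0.15)
  expect_lt(sp$p_linear, 0.05)
  expect_gt(sp$p_nonlinear, 0.10)
  expect_identical(nrow(sp$curve), 50L)

  ## hinge truth mirrors a threshold age effect: nonlinearity flagged
  sim2 <- simulate_cohort(synthetic_config(n = 1000, seed = 22,
    true_log_hr = c(recipient_age_over_50 = 0.06)), seed = 22)
  sp2 <- spline_nonlinearity_test(sim2$design, sim2$outcomes, "recipient_age")
  expect_lt(sp2$p_nonlinear, 0.05)

  ## adjusted (multivariate) mode runs and returns probabilities
  sp3 <- spline_nonlinearity_test(sim$design, sim$outcomes, "donor_age",
                                  adjusted_for = c("donor_male",
                                                   "hla_mismatch"))
  expect_true(sp3$p_nonlinear >= 0 && sp3$p_nonlinear <= 1)

  expect_error(spline_nonlinearity_test(sim$design, sim$outcomes,
                                        "donor_male"), "distinct")
})
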