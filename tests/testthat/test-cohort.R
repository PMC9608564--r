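test_that("cohort CSV round-trip preserves values and missingness", {
  tab <- toy_cohort(n = 8)
  tab$donor_diabetes[c(2, 5)] <- NA
  tab$recipient_esrd_cause[3] <- NA
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(tab, path)
  back <- read_cohort(path)
  expect_equal(back[names(tab)], tab, ignore_attr = TRUE)
  expect_true(all(is.na(back$donor_diabetes[c(2, 5)])))
  expect_true(is.na(back$recipient_esrd_cause[3]))
})

test_that("reader enforces the mandatory schema and flags bad cells", {
  tab <- toy_cohort(n = 3)
  path <- withr::local_tempfile(fileext = ".csv")

  write_cohort(tab[setdiff(names(tab), "outcome")], path)
  expect_error(read_cohort(path), "outcome")

  utils::write.csv(tab[0, ], path, row.names = FALSE)
  expect_error(read_cohort(path), "empty")

  tab2 <- tab
  tab2$donor_diabetes <- c("1", "not-a-number", "0")
  tab2$hla_mismatch[1] <- 9
  utils::write.csv(tab2, path, row.names = FALSE)
  expect_warning(expect_warning(back <- read_cohort(path), "donor_diabetes"),
                 "hla_mismatch")
  expect_true(is.na(back$donor_diabetes[2]))
  expect_true(is.na(back$hla_mismatch[1]))

  tab3 <- tab
  tab3$followup_time[2] <- "unknown"
  utils::write.csv(tab3, path, row.names = FALSE)
  expect_error(read_cohort(path), "followup_time")
})

test_that("inclusion filters follow the four-step sequence", {
  base <- toy_cohort(n = 5)
  base$transplant_year <- 2005
  base$followup_time <- 2
  base$recipient_age <- 40
  base$donor_age <- 40
  base$recipient_years_dialysis <- 2
  ## one violation per step, in order
  base$transplant_year[1] <- 1997
  base$followup_time[2] <- -1
  base$hla_mismatch[3] <- NA
  base$recipient_age[4] <- 17
  res <- apply_inclusion_filters(base)
  expect_identical(res$log$removed, rep(1L, 4))
  expect_identical(res$log$remaining, c(4L, 3L, 2L, 1L))
  expect_identical(res$log$filter,
                   c("window", "consistency", "missing", "pediatric"))
  expect_equal(nrow(res$table), 1)

  clean <- toy_cohort(n = 5)
  res2 <- apply_inclusion_filters(clean)
  expect_true(all(res2$log$removed == 0))
  expect_error(apply_inclusion_filters(clean, window = c(2019, 1998)),
               "window")
})

test_that("filter log conserves record counts on randomized tables", {
  for (s in 1:5) {
    tab <- simulate_cohort(synthetic_config(n = 60, seed = s), seed = s)$cohort
    set.seed(s)
    tab$transplant_year[sample(60, 5)] <- 1995
    tab$recipient_age[sample(60, 5)] <- 15
    tab$hla_mismatch[sample(60, 5)] <- NA
    tab$recipient_years_dialysis[sample(60, 3)] <- -2
    res <- apply_inclusion_filters(tab)
    expect_equal(nrow(tab), nrow(res$table) + sum(res$log$removed))
    expect_true(all(diff(res$log$remaining) <= 0))
  }
})

test_that("outcome coding censors death in the primary mode only", {
  tab <- data.frame(followup_time = c(3, 1, 2),
                    outcome = c("death_functioning", "graft_failure",
                                "censored"))
  dc <- to_death_censored(tab)
  expect_equal(dc$event, c(0, 1, 0))
  ov <- to_death_censored(tab, mode = "overall")
  expect_equal(ov$event, c(1, 1, 0))
  expect_lte(sum(dc$event), sum(ov$event))

  allc <- data.frame(followup_time = 1:3, outcome = rep("censored", 3))
  expect_true(all(to_death_censored(allc)$event == 0))
})

test_that("design matrix emits the 25 candidate columns per their formulas", {
  tab <- toy_cohort(n = 20)
  tab$recipient_years_dialysis[1] <- 3.16
  tab$recipient_age[1] <- 45
  tab$recipient_max_pra[1:2] <- c(55, 50)
  X <- build_design_matrix(tab)
  expect_identical(ncol(X), 25L)
  expect_identical(colnames(X), design_columns()$name)
  expect_false(anyNA(X))
  expect_equal(unname(X[1, "recipient_ln_years_dialysis"]), log(4.16),
               tolerance = 1e-12)
  expect_equal(unname(X[1, "recipient_age_over_50"]), 0)
  expect_equal(unname(X[1:2, "recipient_pra_gt_50"]), c(1, 0))

  ## deterministic and idempotent
  expect_identical(X, build_design_matrix(tab))

  tab$donor_diabetes[3] <- NA
  expect_error(build_design_matrix(tab), "impute")
})

test_that("transformed columns satisfy their formulas on random tables", {
  for (s in 1:4) {
    tab <- toy_cohort(n = 40, seed = s)
    X <- build_design_matrix(tab)
    expect_equal(X[, "recipient_ln_weight"], log(tab$recipient_weight + 1),
                 ignore_attr = TRUE)
    expect_equal(X[, "recipient_age_over_50"],
                 pmax(tab$recipient_age - 50, 0), ignore_attr = TRUE)
    expect_equal(X[, "recipient_pra_gt_50"],
                 as.numeric(tab$recipient_max_pra > 50), ignore_attr = TRUE)
    expect_equal(X[, "esrd_glomerulopathies"] + X[, "esrd_diabetes"] +
                   X[, "esrd_hypertension"],
                 as.numeric(tab$recipient_esrd_cause != "other"),
                 ignore_attr = TRUE)
  }
})

test_that("cohort summary reports means, proportions and missingness", {
  tab <- toy_cohort(n = 8)
  tab$recipient_age <- c(40, 45, 50, 40, 45, 50, 40, 50)
  tab$donor_diabetes <- c(1, 1, 1, 0, NA, NA, 0, 0)
  oc <- data.frame(time = rep(1, 8), event = c(1, 1, 0, 0, 0, 0, 0, 0))
  s <- summarize_cohort(tab, oc)
  age <- s[s$variable == "recipient_age", ]
  expect_equal(age$mean, mean(tab$recipient_age))
  expect_equal(age$sd, sd(tab$recipient_age))
  dd <- s[s$variable == "donor_diabetes", ]
  expect_equal(unique(dd$missing_pct), 25)
  yes <- dd[dd$level == "1", ]
  expect_equal(yes$n, 3)
  expect_equal(yes$pct, 50)
  expect_equal(yes$events, 2)
})
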