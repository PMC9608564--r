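## Independent oracles and small instance generators shared across tests.
## These deliberately use naive implementations (explicit loops, enumeration)
## so they stay independent of the package's vectorized/compiled code paths.

## Brute-force Harrell concordance by pure-R pair enumeration
brute_force_c <- function(score, time, event) {
  n <- length(score)
  conc <- comp <- 0
  for (i in seq_len(n)) {
    if (event[i] != 1) next
    for (j in seq_len(n)) {
      if (j == i) next
      comparable <- time[i] < time[j] ||
        (time[i] == time[j] && event[j] == 0)
      if (!comparable) next
      comp <- comp + 1
      if (score[i] > score[j]) conc <- conc + 1
      else if (score[i] == score[j]) conc <- conc + 0.5
    }
  }
  conc / comp
}

## Breslow-ties Cox partial log-likelihood by direct per-event summation
naive_breslow_loglik <- function(beta, X, time, event) {
  eta <- drop(as.matrix(X) %*% beta)
  ll <- 0
  for (i in which(event == 1)) {
    ll <- ll + eta[i] - log(sum(exp(eta[time >= time[i]])))
  }
  ll
}

## Small random survival instance: Gaussian + binary covariates, exponential
## failure times under proportional hazards, uniform censoring
make_surv_instance <- function(n, p, seed, beta = NULL, censor_max = 3) {
  set.seed(seed)
  X <- cbind(matrix(rnorm(n * ceiling(p / 2)), n),
             matrix(rbinom(n * floor(p / 2), 1, 0.4), n))[, seq_len(p),
                                                          drop = FALSE]
  colnames(X) <- paste0("x", seq_len(p))
  if (is.null(beta)) beta <- rnorm(p, 0, 0.3)
  t_fail <- rexp(n, exp(drop(X %*% beta) - 1))
  cens <- runif(n, 0.05, censor_max)
  list(X = X,
       outcomes = data.frame(time = pmin(t_fail, cens),
                             event = as.integer(t_fail <= cens)),
       beta = beta)
}

## Tiny cohort table used by the cohort-module tests
toy_cohort <- function(n = 6, seed = 7) {
  cfg <- synthetic_config(n = n, seed = seed, missing_rates = numeric(0))
  simulate_cohort(cfg, inject_missing = FALSE)$complete
}

## Default-marginal correlation block used by the imputation tests: weight is
## predictable from sex and age, so forest imputation has signal to use
impute_test_correlation <- function() {
  v <- c("recipient_weight", "recipient_male", "recipient_age")
  m <- matrix(c(1, .65, .30,
                .65, 1, .15,
                .30, .15, 1), 3, 3, dimnames = list(v, v))
  m
}
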