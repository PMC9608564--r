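## Model diagnostics: proportional hazards via scaled Schoenfeld residuals and
## the Grambsch-Therneau chi-square test; log-linearity screening via
## penalized splines (df = 5) in Cox regression.

#' Schoenfeld residuals
#'
#' At each event, the residual is the event subject's covariate vector minus
#' the risk-weighted mean of the covariates over the risk set (weights
#' proportional to `exp(x' beta)`). The scaled version multiplies each residual
#' by `d * V(beta)` (d = number of events) and adds `beta`, giving the working
#' estimate of the time-varying coefficient.
#'
#' @param fit A `graftnet_coxfit`.
#' @param X,outcomes The data the fit was obtained on.
#' @param scaled Return Grambsch-Therneau scaled residuals?
#' @return Matrix (events x variables), rows in event-time order, with the
#'   event times as attribute `time`.
#' @export
schoenfeld_residuals <- function(fit, X, outcomes, scaled = FALSE) {
  X <- as.matrix(X)
  check_outcomes(outcomes, n = nrow(X))
  if (sum(outcomes$event) == 0) stop("no events", call. = FALSE)
  beta <- fit$coefficients
  ord <- order(outcomes$time)
  Xs <- X[ord, , drop = FALSE]
  time <- outcomes$time[ord]
  event <- outcomes$event[ord]
  eta <- drop(Xs %*% beta)
  r <- exp(eta - mean(eta))
  first <- !duplicated(time)
  grp <- cumsum(first)
  S0 <- revcumsum(r)[first]
  S1 <- revcumsum(Xs * r)[first, , drop = FALSE]
  xbar <- S1 / S0
  ev <- which(event == 1)
  res <- Xs[ev, , drop = FALSE] - xbar[grp[ev], , drop = FALSE]
  if (scaled) {
    d <- length(ev)
    res <- d * res %*% fit$vcov +
      matrix(beta, d, length(beta), byrow = TRUE)
  }
  colnames(res) <- colnames(X)
  attr(res, "time") <- time[ev]
  res
}

#' Grambsch-Therneau proportional-hazards test
#'
#' Regresses the scaled Schoenfeld residuals on a transform `g(t)` of event
#' time and tests for zero slope. With `u = sum_k (g_k - gbar) s_k` over the
#' unscaled residuals, the global statistic is
#' `d u' V u / sum (g_k - gbar)^2` on `p` degrees of freedom, and the
#' per-variable statistic is `d (V u)_j^2 / (V_jj sum (g_k - gbar)^2)` on one.
#'
#' @param fit A `graftnet_coxfit`.
#' @param X,outcomes The data the fit was obtained on.
#' @param transform Time transform `g`: `"km"` (`1 - KM(t)`, default),
#'   `"identity"` or `"log"`.
#' @return List of class `graftnet_phtest`: per-variable `table`
#'   (`chisq`, `df`, `p`), `global_chisq`, `global_df`, `global_p`,
#'   `transform`, and the scaled residual matrix for plotting.
#' @export
ph_test <- function(fit, X, outcomes, transform = c("km", "identity", "log")) {
  transform <- match.arg(transform)
  if (sum(outcomes$event) < 2) stop("need at least two events", call. = FALSE)
  s <- schoenfeld_residuals(fit, X, outcomes, scaled = FALSE)
  times <- attr(s, "time")
  g <- switch(transform,
              km = {
                km <- kaplan_meier(outcomes)
                1 - curve_at(km, times)
              },
              identity = times,
              log = log(times))
  gc <- g - mean(g)
  ssg <- sum(gc^2)
  if (ssg == 0) stop("constant time transform over events", call. = FALSE)
  d <- nrow(s)
  V <- fit$vcov
  u <- drop(crossprod(s, gc))
  vu <- drop(V %*% u)
  global <- d * sum(u * vu) / ssg
  per <- d * vu^2 / (diag(V) * ssg)
  p <- length(u)
  tab <- data.frame(variable = colnames(s), chisq = per, df = 1,
                    p = stats::pchisq(per, 1, lower.tail = FALSE))
  rownames(tab) <- NULL
  structure(list(table = tab, global_chisq = global, global_df = p,
                 global_p = stats::pchisq(global, p, lower.tail = FALSE),
                 transform = transform,
                 residuals = schoenfeld_residuals(fit, X, outcomes,
                                                  scaled = TRUE),
                 time = times),
            class = "graftnet_phtest")
}

#' @export
print.graftnet_phtest <- function(x, ...) {
  cat("Grambsch-Therneau proportional-hazards test (transform:",
      x$transform, ")\n")
  print(transform(x$table, chisq = round(chisq, 3), p = signif(p, 3)))
  cat("GLOBAL: chisq =", round(x$global_chisq, 3), "df =", x$global_df,
      "p =", signif(x$global_p, 3), "\n")
  invisible(x)
}

#' Penalized-spline log-linearity check
#'
#' Expands one numeric variable in a penalized cubic B-spline basis with a
#' target effective degrees of freedom (default 5) inside a Cox model,
#' optionally adjusted for other columns, and reports Wald tests for the
#' linear component and for the joint nonlinear contrasts. A significant
#' nonlinear component indicates a departure from the log-linearity the Cox
#' model assumes in that variable.
#'
#' @param X Design matrix or data frame of candidate columns.
#' @param outcomes Data frame with `time` and `event`.
#' @param variable Column to examine (numeric, at least 10 distinct values).
#' @param df Target effective degrees of freedom of the spline.
#' @param adjusted_for Optional character vector of adjustment columns
#'   (multivariate mode); `NULL` gives the univariate screen.
#' @param grid_length Points of the fitted-curve grid.
#' @return List of class `graftnet_spline`: `variable`, `df_target`,
#'   `df_used` (trace-based effective df of the spline term), `p_linear`,
#'   `p_nonlinear`, `chisq_linear`, `chisq_nonlinear`, and `curve`
#'   (grid of covariate values with the fitted log-hazard contribution and
#'   standard errors).
#' @export
spline_nonlinearity_test <- function(X, outcomes, variable, df = 5,
                                     adjusted_for = NULL, grid_length = 50) {
  X <- as.data.frame(X)
  check_outcomes(outcomes, n = nrow(X))
  v <- X[[variable]]
  if (is.null(v)) stop("unknown variable: ", variable, call. = FALSE)
  if (length(unique(v)) < 10)
    stop("need at least 10 distinct values in ", variable, call. = FALSE)
  dat <- data.frame(.time = outcomes$time, .event = outcomes$event, .v = v)
  rhs <- sprintf("survival::pspline(.v, df = %g)", df)
  if (length(adjusted_for)) {
    dat <- cbind(dat, X[adjusted_for])
    rhs <- paste(c(rhs, adjusted_for), collapse = " + ")
  }
  fit <- survival::coxph(
    stats::as.formula(paste("survival::Surv(.time, .event) ~", rhs)),
    data = dat)
  idx <- fit$assign2[[1]]
  pf <- fit$printfun[[1]]
  environment(pf) <- asNamespace("survival")
  res <- pf(fit$coefficients[idx], fit$var[idx, idx, drop = FALSE],
            fit$var2[idx, idx, drop = FALSE], fit$df[1], fit$history[[1]])$coef
  grid <- seq(min(v), max(v), length.out = grid_length)
  nd <- dat[rep(1, grid_length), , drop = FALSE]
  nd$.v <- grid
  for (a in adjusted_for) nd[[a]] <- stats::median(dat[[a]])
  pr <- stats::predict(fit, newdata = nd, type = "terms", se.fit = TRUE)
  structure(list(variable = variable, df_target = df, df_used = fit$df[1],
                 chisq_linear = res["linear", 4],
                 p_linear = res["linear", 6],
                 chisq_nonlinear = res["nonlin", 4],
                 df_nonlinear = res["nonlin", 5],
                 p_nonlinear = res["nonlin", 6],
                 curve = data.frame(x = grid,
                                    term = pr$fit[, 1],
                                    se = pr$se.fit[, 1])),
            class = "graftnet_spline")
}

#' @export
print.graftnet_spline <- function(x, ...) {
  cat("Penalized-spline log-linearity check for", x$variable,
      sprintf("(effective df %.2f)\n", x$df_used))
  cat(sprintf("  linear:    chisq = %.3f, p = %.4f\n",
              x$chisq_linear, x$p_linear))
  cat(sprintf("  nonlinear: chisq = %.3f (df %.2f), p = %.4f\n",
              x$chisq_nonlinear, x$df_nonlinear, x$p_nonlinear))
  invisible(x)
}
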