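## Survival core: Kaplan-Meier with Greenwood intervals, the Mantel-Cox
## log-rank test, an unpenalized Cox fitter maximizing the Breslow-ties
## partial likelihood by Newton-Raphson with step halving, Harrell's
## concordance, the Breslow cumulative baseline hazard and profile survival
## prediction.

## Per-subject gradient/curvature and event-time aggregates of the Breslow
## partial log-likelihood, for rows sorted by increasing time.
cox_breslow_parts <- function(X, time, event, eta, need_hessian = FALSE) {
  n <- length(time)
  eta <- eta - mean(eta)  # invariant shift, numerical guard
  r <- exp(eta)
  first <- !duplicated(time)
  grp <- cumsum(first)
  S0 <- revcumsum(r)[first]
  d <- as.vector(rowsum(as.numeric(event), grp))
  loglik <- sum(eta[event == 1]) - sum(d * log(S0))
  A <- cumsum(d / S0)[grp]
  B <- cumsum(d / S0^2)[grp]
  g <- event - r * A
  w <- r * A - r * r * B
  out <- list(loglik = loglik, grad_eta = g, weight = w)
  if (need_hessian) {
    p <- ncol(X)
    rX <- X * r
    S1 <- revcumsum(rX)[first, , drop = FALSE]
    sx <- rowsum(X * event, grp)
    U <- colSums(sx) - colSums((d / S0) * S1)
    pair <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
    P <- rX[, pair[, 1], drop = FALSE] * X[, pair[, 2], drop = FALSE]
    S2 <- revcumsum(P)[first, , drop = FALSE]
    M <- S1 / S0
    hvec <- colSums((d / S0) * S2) -
      colSums(d * (M[, pair[, 1], drop = FALSE] * M[, pair[, 2], drop = FALSE]))
    H <- matrix(0, p, p)
    H[upper.tri(H, diag = TRUE)] <- hvec
    H <- H + t(H) - diag(diag(H), p)
    out$score <- U
    out$info <- H  # observed information (minus Hessian of loglik)
  }
  out
}

#' Fit a Cox proportional-hazards model
#'
#' Maximizes the Breslow-ties partial log-likelihood by Newton-Raphson with
#' step halving. Convergence is declared when the log-likelihood improves by
#' less than `tol`; non-convergence is an error unless a monotone likelihood
#' (complete separation, detected through diverging coefficients) was flagged,
#' in which case the fit is returned with `separation = TRUE` and a warning.
#' Inference is Wald: `HR = exp(beta)`, 95% CI `exp(beta +/- 1.96 se)`.
#'
#' @param X Numeric design matrix (no missing values, no constant columns).
#' @param outcomes Data frame with `time` and `event`.
#' @param max_iter Maximum Newton iterations.
#' @param tol Convergence tolerance on the log-likelihood change.
#' @return Object of class `graftnet_coxfit`: coefficients, `vcov`, `se`,
#'   `hr` with `ci_lower`/`ci_upper`, Wald `p`, `loglik` (final), trace of the
#'   per-iteration log-likelihood, score vector at the optimum, `n`, `nevent`.
#' @export
cox_fit <- function(X, outcomes, max_iter = 50, tol = 1e-9) {
  X <- as.matrix(X)
  check_outcomes(outcomes, n = nrow(X))
  if (anyNA(X)) stop("design matrix contains missing values", call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance column(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "),
         "; coefficient not estimable", call. = FALSE)
  p <- ncol(X)
  nevent <- sum(outcomes$event)
  if (nevent < p + 1)
    warning("only ", nevent, " events for ", p, " coefficients")
  ord <- order(outcomes$time)
  Xs <- X[ord, , drop = FALSE]
  time <- outcomes$time[ord]
  event <- outcomes$event[ord]

  beta <- rep(0, p)
  parts <- cox_breslow_parts(Xs, time, event, drop(Xs %*% beta),
                             need_hessian = TRUE)
  trace <- parts$loglik
  separation <- FALSE
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    step <- tryCatch(solve(parts$info, parts$score), error = function(e)
      stop("singular information matrix; check for collinear columns",
           call. = FALSE))
    new_beta <- beta + step
    new_parts <- cox_breslow_parts(Xs, time, event, drop(Xs %*% new_beta),
                                   need_hessian = TRUE)
    halvings <- 0
    while (!is.finite(new_parts$loglik) || new_parts$loglik < parts$loglik) {
      halvings <- halvings + 1
      if (halvings > 30) break
      new_beta <- (beta + new_beta) / 2
      new_parts <- cox_breslow_parts(Xs, time, event, drop(Xs %*% new_beta),
                                     need_hessian = TRUE)
    }
    delta <- new_parts$loglik - parts$loglik
    beta <- new_beta
    parts <- new_parts
    trace <- c(trace, parts$loglik)
    if (max(abs(beta)) > 20) separation <- TRUE
    if (is.finite(delta) && abs(delta) < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    if (separation)
      warning("monotone partial likelihood (separation) suspected; ",
              "coefficients diverging")
    else
      stop("Newton-Raphson did not converge in ", max_iter,
           " iterations; log-likelihood trace: ",
           paste(signif(trace, 8), collapse = ", "), call. = FALSE)
  }
  V <- solve(parts$info)
  se <- sqrt(diag(V))
  z <- beta / se
  names(beta) <- colnames(X)
  dimnames(V) <- list(colnames(X), colnames(X))
  structure(list(coefficients = beta, vcov = V, se = stats::setNames(se, colnames(X)),
                 hr = exp(beta), ci_lower = exp(beta - 1.96 * se),
                 ci_upper = exp(beta + 1.96 * se),
                 p = 2 * stats::pnorm(-abs(z)), loglik = parts$loglik,
                 loglik_trace = trace, score = parts$score,
                 n = nrow(X), nevent = nevent, iterations = it,
                 converged = converged, separation = separation),
            class = "graftnet_coxfit")
}

#' @export
print.graftnet_coxfit <- function(x, ...) {
  cat("Cox proportional-hazards fit (Breslow ties), n =", x$n,
      ", events =", x$nevent, "\n")
  tab <- data.frame(HR = round(x$hr, 3), lower = round(x$ci_lower, 3),
                    upper = round(x$ci_upper, 3), p = signif(x$p, 3))
  print(tab)
  invisible(x)
}

#' Harrell's concordance index
#'
#' Fraction of censoring-comparable pairs ranked correctly by the risk score
#' (higher score, higher risk). A pair with an event at `t_i` is comparable
#' with any subject known to survive past `t_i`; tied scores earn half credit;
#' two events at the same time are incomparable.
#'
#' @param score Finite numeric risk scores.
#' @param outcomes Data frame with `time` and `event`.
#' @return Concordance in `[0, 1]`.
#' @export
harrell_c <- function(score, outcomes) {
  check_outcomes(outcomes, n = length(score))
  if (any(!is.finite(score))) stop("risk scores must be finite", call. = FALSE)
  res <- concordance_pairs(as.numeric(outcomes$time),
                           as.integer(outcomes$event), as.numeric(score))
  if (res$comparable == 0)
    stop("no comparable pairs; concordance undefined", call. = FALSE)
  res$concordant / res$comparable
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate with Greenwood variance and confidence limits on the
#' complementary log-log scale (via [survival::survfit]).
#'
#' @param outcomes Data frame with `time` and `event`.
#' @param conf_level Confidence level.
#' @return Data frame of class `graftnet_km`: `time`, `n_risk`, `n_event`,
#'   `surv`, `std_err`, `lower`, `upper`.
#' @export
kaplan_meier <- function(outcomes, conf_level = 0.95) {
  check_outcomes(outcomes)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = outcomes,
                          conf.type = "log-log", conf.int = conf_level)
  out <- data.frame(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
                    surv = sf$surv, std_err = sf$std.err * sf$surv,
                    lower = ifelse(is.na(sf$lower) & sf$surv == 1, 1, sf$lower),
                    upper = ifelse(is.na(sf$upper) & sf$surv == 1, 1, sf$upper))
  class(out) <- c("graftnet_km", "data.frame")
  out
}

#' Evaluate a step survival curve at given times
#'
#' @param curve A `graftnet_km` curve or any data frame with `time` and a value
#'   column.
#' @param times Times to evaluate at.
#' @param value Column to read (default `surv`).
#' @return Right-continuous step-function values (1 before the first step for
#'   survival curves, 0 for cumulative hazards).
#' @export
curve_at <- function(curve, times, value = "surv") {
  idx <- findInterval(times, curve$time)
  start <- if (value == "surv") 1 else 0
  c(start, curve[[value]])[idx + 1L]
}

#' Mantel-Cox (log-rank) test
#'
#' @param outcomes Data frame with `time` and `event`.
#' @param group Group labels (at least two non-empty groups).
#' @return List with `chisq`, `df`, `p`.
#' @export
logrank_test <- function(outcomes, group) {
  check_outcomes(outcomes, n = length(group))
  if (length(unique(group)) < 2)
    stop("log-rank test needs at least two groups", call. = FALSE)
  d <- data.frame(time = outcomes$time, event = outcomes$event,
                  group = factor(group))
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  df <- length(sd_$n) - 1
  list(chisq = unname(sd_$chisq), df = df,
       p = stats::pchisq(sd_$chisq, df, lower.tail = FALSE))
}

#' Breslow cumulative baseline hazard
#'
#' `H0(t) = sum over event times t_k <= t of d_k / sum_{j in risk set}
#' exp((x_j - x_ref)' beta)`, centered at a reference covariate profile so the
#' "baseline" curve is the predicted curve of the reference case.
#'
#' @param fit A `graftnet_coxfit` (or any list with `coefficients`).
#' @param X Design matrix the fit was obtained on.
#' @param outcomes Matching outcome table.
#' @param reference Named reference profile; defaults to all-zero. Must cover
#'   the fitted columns.
#' @return Data frame of class `graftnet_basehaz`: `time` (distinct event
#'   times), `hazard` (cumulative), with the reference stored as an attribute.
#' @export
breslow_baseline <- function(fit, X, outcomes, reference = NULL) {
  X <- as.matrix(X)
  check_outcomes(outcomes, n = nrow(X))
  beta <- fit$coefficients
  ref <- stats::setNames(rep(0, ncol(X)), colnames(X))
  if (!is.null(reference)) {
    if (!all(names(reference) %in% colnames(X)))
      stop("reference profile names do not match design columns", call. = FALSE)
    ref[names(reference)] <- reference
  }
  ord <- order(outcomes$time)
  time <- outcomes$time[ord]
  event <- outcomes$event[ord]
  eta <- drop((X[ord, , drop = FALSE] %*% beta)) - sum(ref * beta)
  r <- exp(eta)
  first <- !duplicated(time)
  grp <- cumsum(first)
  S0 <- revcumsum(r)[first]
  d <- as.vector(rowsum(as.numeric(event), grp))
  keep <- d > 0
  out <- data.frame(time = time[first][keep],
                    hazard = cumsum(d[keep] / S0[keep]))
  attr(out, "reference") <- ref
  class(out) <- c("graftnet_basehaz", "data.frame")
  out
}

#' Predict a survival curve for a covariate profile
#'
#' `S(t | x) = exp(-H0(t) exp((x - x_ref)' beta))` as a step function over the
#' event times of the baseline.
#'
#' @param baseline A `graftnet_basehaz`.
#' @param fit The `graftnet_coxfit` the baseline was computed from.
#' @param profile Named covariate profile covering the fitted columns;
#'   unnamed columns default to the baseline's reference value.
#' @return Data frame of class `graftnet_curve`: `time`, `surv`.
#' @export
predict_survival <- function(baseline, fit, profile = NULL) {
  beta <- fit$coefficients
  ref <- attr(baseline, "reference")
  x <- ref
  if (!is.null(profile)) {
    if (!all(names(profile) %in% names(ref)))
      stop("profile names do not match fitted columns", call. = FALSE)
    x[names(profile)] <- profile
  }
  risk <- exp(sum((x - ref) * beta))
  out <- data.frame(time = baseline$time, surv = exp(-baseline$hazard * risk))
  class(out) <- c("graftnet_curve", "data.frame")
  out
}
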