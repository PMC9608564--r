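## Elastic-net penalized Cox regression by cyclic coordinate descent on the
## quadratic (IRLS) approximation of the Breslow partial likelihood, solved
## pathwise over a decreasing penalty grid with warm starts. The objective is
##   f(beta) = -(1/n) l_Breslow(beta)
##             + lambda * (alpha |beta|_1 + (1-alpha)/2 |beta|_2^2)
## with all columns centered and scaled to unit (1/n) variance internally and
## coefficients reported on the original covariate scale.

#' Soft-thresholding operator
#'
#' `sign(z) * max(|z| - gamma, 0)`, the scalar kernel of the coordinate
#' descent update.
#'
#' @param z Numeric.
#' @param gamma Threshold, `>= 0`.
#' @return Thresholded value.
#' @export
soft_threshold <- function(z, gamma) {
  if (any(gamma < 0)) stop("gamma must be >= 0", call. = FALSE)
  sign(z) * pmax(abs(z) - gamma, 0)
}

## standardize to mean 0, variance 1 with the 1/n variance convention
standardize_design <- function(X) {
  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  scale <- sqrt(colMeans(Xc^2))
  if (any(scale == 0))
    stop("zero-variance column(s): ",
         paste(colnames(X)[scale == 0], collapse = ", "), call. = FALSE)
  list(X = sweep(Xc, 2, scale, "/"), center = center, scale = scale)
}

## Precomputed risk-set structure for repeated Breslow partial-likelihood
## evaluations on one sorted data set: returns a function of eta giving
## loglik, per-subject gradient and diagonal curvature.
cox_likelihood_fun <- function(time, event) {
  first <- !duplicated(time)
  grp <- cumsum(first)
  d <- as.vector(rowsum(as.numeric(event), grp))
  is_event <- event == 1
  function(eta) {
    eta <- eta - mean(eta)
    r <- exp(eta)
    S0 <- rev(cumsum(rev(r)))[first]
    A <- cumsum(d / S0)[grp]
    B <- cumsum(d / S0^2)[grp]
    rA <- r * A
    list(loglik = sum(eta[is_event]) - sum(d * log(S0)),
         grad_eta = event - rA, weight = rA - r * r * B)
  }
}

#' Penalty grid for the elastic-net Cox path
#'
#' `lambda_max` is the smallest penalty at which all coefficients are zero:
#' the largest absolute gradient of the scaled negative partial log-likelihood
#' at `beta = 0`, divided by `alpha`. The grid is `n_lambda` points log-spaced
#' down to `min_ratio * lambda_max`.
#'
#' @param X Design matrix (standardized internally).
#' @param outcomes Data frame with `time` and `event`.
#' @param alpha Elastic-net mixing weight in `(0, 1]`.
#' @param n_lambda Grid length.
#' @param min_ratio Smallest grid value relative to `lambda_max`.
#' @return Decreasing numeric vector of penalties.
#' @export
lambda_path <- function(X, outcomes, alpha = 0.95, n_lambda = 100,
                        min_ratio = 0.05) {
  if (alpha <= 0 || alpha > 1)
    stop("alpha must lie in (0, 1]; alpha = 0 has no finite lambda_max",
         call. = FALSE)
  std <- standardize_design(as.matrix(X))
  check_outcomes(outcomes, n = nrow(X))
  ord <- order(outcomes$time)
  Xs <- std$X[ord, , drop = FALSE]
  parts <- cox_breslow_parts(Xs, outcomes$time[ord], outcomes$event[ord],
                             rep(0, nrow(Xs)))
  n <- nrow(Xs)
  lambda_max <- max(abs(crossprod(Xs, parts$grad_eta))) / (n * alpha)
  exp(seq(log(lambda_max), log(min_ratio * lambda_max),
          length.out = n_lambda))
}

#' Fit the elastic-net Cox coefficient path
#'
#' For each penalty on the grid (warm-started from the previous solution) the
#' outer loop builds the weighted-least-squares approximation of the Breslow
#' partial likelihood at the current coefficients and the inner loop solves it
#' by cyclic coordinate descent with an active-set strategy and exact
#' soft-thresholded zeros. The outer loop stops when the largest coefficient
#' change falls below `thresh`; a step that would increase the penalized
#' objective is halved, so the objective is non-increasing across outer
#' iterations.
#'
#' @param X Design matrix (complete).
#' @param outcomes Data frame with `time` and `event` (at least two events).
#' @param alpha Elastic-net mixing weight in `(0, 1]`.
#' @param lambda Penalty grid; defaults to [lambda_path()].
#' @param n_lambda,min_ratio Grid parameters when `lambda` is `NULL`.
#' @param thresh Convergence threshold on the coefficient change
#'   (standardized scale).
#' @param max_outer Maximum outer iterations per grid point.
#' @return Object of class `graftnet_coxnet`: `lambda`, `beta` (columns of the
#'   coefficient matrix on the original scale, one per grid point), `df`
#'   (nonzero counts), `alpha`, `converged` flags, standardization
#'   `center`/`scale`, and the per-point outer objective traces.
#' @export
coxnet_fit <- function(X, outcomes, alpha = 0.95, lambda = NULL,
                       n_lambda = 100, min_ratio = 0.05,
                       thresh = 1e-7, max_outer = 100) {
  X <- as.matrix(X)
  check_outcomes(outcomes, n = nrow(X))
  if (anyNA(X)) stop("design matrix contains missing values", call. = FALSE)
  if (sum(outcomes$event) < 2) stop("need at least two events", call. = FALSE)
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]", call. = FALSE)
  if (is.null(lambda))
    lambda <- lambda_path(X, outcomes, alpha, n_lambda, min_ratio)
  if (is.unsorted(rev(lambda))) lambda <- sort(lambda, decreasing = TRUE)

  std <- standardize_design(X)
  ord <- order(outcomes$time)
  Xs <- std$X[ord, , drop = FALSE]
  time <- outcomes$time[ord]
  event <- outcomes$event[ord]
  if (length(unique(time)) == 1 && all(event == 1))
    stop("degenerate risk sets: all events tied at a single time", call. = FALSE)
  n <- nrow(Xs)
  p <- ncol(Xs)
  lik <- cox_likelihood_fun(time, event)
  penalty <- function(b, lam)
    lam * (alpha * sum(abs(b)) + (1 - alpha) / 2 * sum(b^2))

  beta <- rep(0, p)
  eta <- rep(0, n)
  parts <- lik(eta)
  beta_mat <- matrix(0, p, length(lambda),
                     dimnames = list(colnames(X), NULL))
  converged <- logical(length(lambda))
  traces <- vector("list", length(lambda))
  for (k in seq_along(lambda)) {
    lam <- lambda[k]
    obj <- -parts$loglik / n + penalty(beta, lam)
    trace <- obj
    ok <- FALSE
    for (outer in seq_len(max_outer)) {
      w <- pmax(parts$weight, 1e-8)
      z <- eta + parts$grad_eta / w
      sol <- cd_enet(Xs, w, z, beta, lam, alpha,
                     tol = thresh / 10, maxit = 5000L)
      new_beta <- sol$beta
      new_eta <- drop(Xs %*% new_beta)
      new_parts <- lik(new_eta)
      new_obj <- -new_parts$loglik / n + penalty(new_beta, lam)
      halvings <- 0
      while (new_obj > obj + 1e-12 && halvings < 20) {
        new_beta <- (beta + new_beta) / 2
        new_eta <- drop(Xs %*% new_beta)
        new_parts <- lik(new_eta)
        new_obj <- -new_parts$loglik / n + penalty(new_beta, lam)
        halvings <- halvings + 1
      }
      delta <- max(abs(new_beta - beta))
      beta <- new_beta
      eta <- new_eta
      parts <- new_parts
      obj <- new_obj
      trace <- c(trace, obj)
      if (delta < thresh) { ok <- TRUE; break }
    }
    converged[k] <- ok
    traces[[k]] <- trace
    beta_mat[, k] <- beta / std$scale
  }
  if (!all(converged))
    warning(sum(!converged), " grid point(s) did not converge; flagged")
  structure(list(lambda = lambda, beta = beta_mat,
                 df = colSums(beta_mat != 0), alpha = alpha,
                 converged = converged, center = std$center,
                 scale = std$scale, n = n, objective_trace = traces),
            class = "graftnet_coxnet")
}

#' @export
print.graftnet_coxnet <- function(x, ...) {
  cat("Elastic-net Cox path: alpha =", x$alpha, ",", length(x$lambda),
      "penalties, df range", min(x$df), "-", max(x$df), "\n")
  invisible(x)
}

## locate a penalty on the grid (relative tolerance), error otherwise
match_lambda <- function(path, lambda) {
  rel <- abs(path$lambda - lambda) / max(lambda, 1e-12)
  k <- which.min(rel)
  if (rel[k] > 1e-8)
    stop("lambda = ", signif(lambda, 6), " is not on the grid; nearest is ",
         signif(path$lambda[k], 6), call. = FALSE)
  k
}

#' Selected variables at a penalty
#'
#' Columns with exactly nonzero coefficients at a grid point of the path.
#'
#' @param path A `graftnet_coxnet`.
#' @param lambda A penalty on the grid (matched within relative 1e-8).
#' @return Character vector of column names.
#' @export
nonzero_set <- function(path, lambda) {
  k <- match_lambda(path, lambda)
  rownames(path$beta)[path$beta[, k] != 0]
}

#' Verify the elastic-net KKT conditions along a path
#'
#' Independent certificate, computed from the exact gradient of the scaled
#' negative Breslow partial log-likelihood (not the solver's quadratic
#' approximation): at each grid point, `|g_j| <= lambda * alpha + tol` for
#' zero coefficients and `|g_j + lambda * (1 - alpha) * beta_j +
#' lambda * alpha * sign(beta_j)| <= tol` for nonzero ones, on the
#' standardized scale.
#'
#' @param path A `graftnet_coxnet`.
#' @param X,outcomes The data the path was fit on.
#' @param tol Certificate tolerance.
#' @return List with `ok` (logical per grid point) and `worst` (largest
#'   violation per grid point).
#' @export
coxnet_kkt_check <- function(path, X, outcomes, tol = 1e-6) {
  X <- as.matrix(X)
  Xs <- sweep(sweep(X, 2, path$center), 2, path$scale, "/")
  ord <- order(outcomes$time)
  Xs <- Xs[ord, , drop = FALSE]
  time <- outcomes$time[ord]
  event <- outcomes$event[ord]
  n <- nrow(Xs)
  ok <- logical(length(path$lambda))
  worst <- numeric(length(path$lambda))
  for (k in seq_along(path$lambda)) {
    lam <- path$lambda[k]
    b <- path$beta[, k] * path$scale  # standardized-scale coefficients
    parts <- cox_breslow_parts(Xs, time, event, drop(Xs %*% b))
    g <- -drop(crossprod(Xs, parts$grad_eta)) / n  # grad of -(1/n) loglik
    viol <- ifelse(b == 0,
                   pmax(abs(g) - lam * path$alpha, 0),
                   abs(g + lam * (1 - path$alpha) * b +
                         lam * path$alpha * sign(b)))
    worst[k] <- max(viol)
    ok[k] <- worst[k] <= tol
  }
  list(ok = ok, worst = worst)
}
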