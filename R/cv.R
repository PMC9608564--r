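## Repeated cross-validated selection: K-fold CV of the elastic-net Cox path
## scored by held-out Harrell's C, the one-standard-deviation penalty rule,
## and majority voting over repeated fold draws.

## event-stratified fold assignment so every fold keeps roughly the global
## event rate
stratified_folds <- function(event, K) {
  fold <- integer(length(event))
  for (g in c(0, 1)) {
    idx <- which(event == g)
    fold[idx] <- sample(rep_len(sample(K), length(idx)))
  }
  fold
}

#' Cross-validated elastic-net Cox path
#'
#' Fits the path on each set of K-1 training folds and scores the held-out
#' fold's linear predictors with Harrell's concordance at every penalty. Folds
#' are stratified by event status; an assignment leaving a fold without events
#' is redrawn (up to 10 attempts). The mean held-out C per penalty is the
#' across-fold average, with both the across-fold SD and the SE of the mean
#' retained for the one-SD rule.
#'
#' @param X Design matrix.
#' @param outcomes Data frame with `time` and `event`.
#' @param K Number of folds (>= 2).
#' @param alpha Elastic-net mixing weight.
#' @param lambda Penalty grid; defaults to the full-data [lambda_path()].
#' @param seed Fold-assignment seed.
#' @param ... Passed to [coxnet_fit()].
#' @return Object of class `graftnet_cv`: `lambda`, `cvm` (mean held-out C),
#'   `cvsd` (fold SD), `cvse` (SE of the mean), `lambda_opt`, `lambda_1se`
#'   (default `"se"` rule), `K`, `seed`, `fold` assignment.
#' @export
cv_coxnet <- function(X, outcomes, K = 10, alpha = 0.95, lambda = NULL,
                      seed = NULL, ...) {
  X <- as.matrix(X)
  check_outcomes(outcomes, n = nrow(X))
  if (K < 2) stop("K must be >= 2", call. = FALSE)
  if (K > nrow(X)) stop("more folds than observations", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(lambda)) lambda <- lambda_path(X, outcomes, alpha = alpha)
  for (attempt in 1:10) {
    fold <- stratified_folds(outcomes$event, K)
    ev_per_fold <- tapply(outcomes$event, fold, sum)
    n_per_fold <- tabulate(fold, K)
    if (all(ev_per_fold >= 1) && all(n_per_fold >= 2)) break
    if (attempt == 10)
      stop("could not build ", K, " folds with events in each; too few events",
           call. = FALSE)
  }
  cmat <- matrix(NA_real_, K, length(lambda))
  for (k in seq_len(K)) {
    tr <- fold != k
    path <- coxnet_fit(X[tr, , drop = FALSE], outcomes[tr, , drop = FALSE],
                       alpha = alpha, lambda = lambda, ...)
    eta_test <- X[!tr, , drop = FALSE] %*% path$beta
    out_test <- outcomes[!tr, , drop = FALSE]
    cmat[k, ] <- apply(eta_test, 2, harrell_c, outcomes = out_test)
  }
  cvm <- colMeans(cmat)
  cvsd <- apply(cmat, 2, stats::sd)
  curve <- structure(list(lambda = lambda, cvm = cvm, cvsd = cvsd,
                          cvse = cvsd / sqrt(K), K = K, seed = seed,
                          fold = fold, fold_c = cmat),
                     class = "graftnet_cv")
  curve$lambda_opt <- lambda[pick_opt_index(curve)]
  curve$lambda_1se <- pick_lambda_1se(curve)
  curve
}

## index of the best mean C; ties broken toward the larger penalty
pick_opt_index <- function(curve) {
  which(curve$cvm == max(curve$cvm))[1]
}

#' One-standard-deviation penalty rule
#'
#' Returns the largest penalty whose mean cross-validated concordance is
#' within one dispersion unit of the maximum, where the dispersion at the
#' optimum is either the across-fold standard deviation (`rule = "sd"`) or the
#' standard error of the fold mean (`rule = "se"`, default).
#'
#' @param curve A `graftnet_cv`.
#' @param rule `"se"` or `"sd"`.
#' @return The selected penalty.
#' @export
pick_lambda_1se <- function(curve, rule = c("se", "sd")) {
  rule <- match.arg(rule)
  opt <- pick_opt_index(curve)
  disp <- if (rule == "sd") curve$cvsd[opt] else curve$cvse[opt]
  threshold <- curve$cvm[opt] - disp
  max(curve$lambda[curve$cvm >= threshold])
}

#' @export
print.graftnet_cv <- function(x, ...) {
  opt <- pick_opt_index(x)
  cat(sprintf("%d-fold CV of the elastic-net Cox path: best C = %.3f at lambda = %.4g; lambda_1se = %.4g\n",
              x$K, x$cvm[opt], x$lambda_opt, x$lambda_1se))
  invisible(x)
}

#' Stability selection over repeated cross-validation
#'
#' Repeats the cross-validated penalty choice with fresh fold assignments,
#' records which variables have nonzero coefficients on the full-data path at
#' each repeat's one-SD penalty, and votes in the variables selected in more
#' than `threshold` of the repeats. Child seeds are derived from the master
#' seed by a counter, so earlier repeats are unchanged when `n_repeats` grows.
#'
#' @param X Design matrix.
#' @param outcomes Data frame with `time` and `event`.
#' @param n_repeats Number of repeated CV draws.
#' @param K Folds per repeat.
#' @param alpha Elastic-net mixing weight.
#' @param threshold Vote fraction; selection requires a count strictly greater
#'   than `threshold * n_repeats`.
#' @param rule Dispersion rule for [pick_lambda_1se()].
#' @param seed Master seed.
#' @param ... Passed to [coxnet_fit()].
#' @return Object of class `graftnet_selection`: per-variable `counts`,
#'   `n_repeats`, `threshold`, `voted` (character vector), `lambda_chosen`
#'   per repeat, the full-data `path`, `alpha`, `rule`, `seed`.
#' @export
stability_select <- function(X, outcomes, n_repeats = 1000, K = 10,
                             alpha = 0.95, threshold = 0.5,
                             rule = c("se", "sd"), seed = 1, ...) {
  rule <- match.arg(rule)
  if (n_repeats < 1) stop("n_repeats must be >= 1", call. = FALSE)
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie in (0, 1)", call. = FALSE)
  X <- as.matrix(X)
  lambda <- lambda_path(X, outcomes, alpha = alpha)
  path <- coxnet_fit(X, outcomes, alpha = alpha, lambda = lambda, ...)
  counts <- stats::setNames(integer(ncol(X)), colnames(X))
  lambda_chosen <- numeric(n_repeats)
  for (r in seq_len(n_repeats)) {
    curve <- tryCatch(
      cv_coxnet(X, outcomes, K = K, alpha = alpha, lambda = lambda,
                seed = child_seed(seed, r), ...),
      error = function(e) stop("repeat ", r, ": ", conditionMessage(e),
                               call. = FALSE))
    lam <- pick_lambda_1se(curve, rule = rule)
    lambda_chosen[r] <- lam
    sel <- nonzero_set(path, lam)
    counts[sel] <- counts[sel] + 1L
  }
  voted <- names(counts)[counts > threshold * n_repeats]
  structure(list(counts = counts, n_repeats = n_repeats,
                 threshold = threshold, voted = voted,
                 lambda_chosen = lambda_chosen, path = path, alpha = alpha,
                 rule = rule, seed = seed, K = K),
            class = "graftnet_selection")
}

#' @export
print.graftnet_selection <- function(x, ...) {
  cat("Stability selection:", x$n_repeats, "repeats of", x$K,
      "-fold CV (alpha =", x$alpha, ", rule =", x$rule, ")\n")
  ord <- order(x$counts, decreasing = TRUE)
  tab <- data.frame(variable = names(x$counts)[ord],
                    count = as.integer(x$counts[ord]),
                    voted = names(x$counts)[ord] %in% x$voted)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Out-of-sample concordance of a fitted Cox model
#'
#' @param fit A `graftnet_coxfit`.
#' @param X_test Test design matrix with the fitted columns.
#' @param outcomes_test Test outcome table.
#' @return Harrell's C on the test linear predictors.
#' @export
evaluate_holdout <- function(fit, X_test, outcomes_test) {
  X_test <- as.matrix(X_test)
  cols <- names(fit$coefficients)
  if (!all(cols %in% colnames(X_test)))
    stop("test design lacks fitted column(s): ",
         paste(setdiff(cols, colnames(X_test)), collapse = ", "),
         call. = FALSE)
  harrell_c(drop(X_test[, cols, drop = FALSE] %*% fit$coefficients),
            outcomes_test)
}
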