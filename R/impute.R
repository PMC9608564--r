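## Iterative random-forest imputation (the MissForest scheme) over the cohort
## covariates, with out-of-bag errors and a convergence trace.

impute_var_types <- function(table) {
  sch <- cohort_schema()
  sch <- sch[sch$role == "covariate", ]
  sch <- sch[sch$name %in% names(table), ]
  stats::setNames(sch$type, sch$name)
}

## column mean / mode starting fill
initial_fill <- function(x, type) {
  if (type %in% c("binary", "category", "integer_mode")) {
    tab <- table(x[!is.na(x)])
    names(tab)[which.max(tab)]
  } else {
    mean(x, na.rm = TRUE)
  }
}

#' Mean/mode imputation baseline
#'
#' Fills every missing covariate cell with the column mean (numerics) or mode
#' (binaries and categoricals). Used as the reference the random-forest
#' imputation must beat.
#'
#' @param table Cohort data frame.
#' @return Completed table.
#' @export
baseline_impute <- function(table) {
  types <- impute_var_types(table)
  for (v in names(types)) {
    idx <- is.na(table[[v]])
    if (!any(idx)) next
    if (all(idx)) stop("variable ", v, " has no observed values", call. = FALSE)
    fill <- initial_fill(table[[v]],
                         if (types[[v]] %in% c("binary", "category"))
                           "binary" else "numeric")
    if (types[[v]] %in% c("binary", "integer"))
      fill <- as.numeric(fill)
    table[[v]][idx] <- fill
  }
  table
}

#' MissForest imputation
#'
#' Iterative random-forest imputation: missing cells are initialized with the
#' column mean/mode, then variables are visited in ascending order of
#' missingness; each is regressed (random forest) on all other covariates over
#' its observed rows and its missing rows are predicted. After each full sweep
#' the difference statistics are computed — `delta_numeric =
#' sum((new - old)^2) / sum(new^2)` over imputed numeric cells and
#' `delta_categorical` = fraction of imputed categorical cells that changed —
#' and the algorithm stops the first time either statistic increases, returning
#' the sweep *before* the increase. Binary covariates are imputed as
#' classification targets and mapped back to 0/1.
#'
#' `followup_time` and `outcome` are excluded from the predictor set by default
#' to avoid outcome leakage into the imputed covariates; set
#' `use_outcome = TRUE` to include them.
#'
#' @param table Cohort data frame with missing covariate cells.
#' @param max_iter Maximum number of sweeps.
#' @param n_trees Trees per forest.
#' @param seed Seed (forests are single-threaded for determinism).
#' @param use_outcome Include follow-up time and event status as predictors?
#' @return List of class `graftnet_imputation`: `table` (completed),
#'   `iterations`, `oob_error` (per-variable out-of-bag NRMSE or
#'   misclassification rate), `trace` (per-sweep difference statistics).
#' @export
missforest_impute <- function(table, max_iter = 10, n_trees = 100, seed = 1,
                              use_outcome = FALSE) {
  if (!is.data.frame(table)) stop("`table` must be a data frame", call. = FALSE)
  types <- impute_var_types(table)
  if (!length(types)) stop("no cohort covariates found", call. = FALSE)
  na_idx <- lapply(names(types), function(v) which(is.na(table[[v]])))
  names(na_idx) <- names(types)
  n_missing <- vapply(na_idx, length, integer(1))
  if (any(n_missing == nrow(table)))
    stop("variable(s) with zero observed values: ",
         paste(names(types)[n_missing == nrow(table)], collapse = ", "),
         call. = FALSE)
  targets <- names(types)[n_missing > 0]
  if (!length(targets)) {
    return(structure(list(table = table, iterations = 1L,
                          oob_error = numeric(0),
                          trace = data.frame(iteration = 1L, delta_numeric = 0,
                                             delta_categorical = 0)),
                     class = "graftnet_imputation"))
  }
  if (!any(n_missing == 0))
    stop("at least one fully observed covariate is required", call. = FALSE)
  targets <- targets[order(n_missing[targets])]

  ## working frame: factors for categorical targets/predictors
  to_factor <- names(types)[types %in% c("binary", "category")]
  work <- table[names(types)]
  predictors_extra <- if (use_outcome) {
    data.frame(followup_time = table$followup_time,
               event = as.integer(table$outcome == "graft_failure"))
  } else NULL

  ## initial mean/mode fill
  for (v in targets) {
    fill <- initial_fill(work[[v]], if (v %in% to_factor) "binary" else "numeric")
    if (types[[v]] %in% c("binary", "integer")) fill <- as.numeric(fill)
    work[[v]][na_idx[[v]]] <- fill
  }

  as_model_frame <- function(w) {
    for (v in to_factor) w[[v]] <- factor(w[[v]])
    if (!is.null(predictors_extra)) w <- cbind(w, predictors_extra)
    w
  }

  numeric_targets <- targets[!types[targets] %in% c("binary", "category")]
  cat_targets <- targets[types[targets] %in% c("binary", "category")]

  trace <- data.frame(iteration = integer(0), delta_numeric = numeric(0),
                      delta_categorical = numeric(0))
  prev <- list(d_num = Inf, d_cat = Inf)
  best <- work
  oob <- stats::setNames(rep(NA_real_, length(targets)), targets)
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    old <- work
    for (v in targets) {
      mf <- as_model_frame(work)
      obs <- setdiff(seq_len(nrow(mf)), na_idx[[v]])
      ydat <- mf[obs, , drop = FALSE]
      ydat[[v]] <- if (v %in% to_factor)
        factor(table[[v]][obs]) else table[[v]][obs]
      fit <- ranger::ranger(
        stats::as.formula(paste("`", v, "` ~ .", sep = "")),
        data = ydat, num.trees = n_trees, num.threads = 1,
        seed = child_seed(seed, iter * 1000 + match(v, targets)),
        respect.unordered.factors = "order")
      pred <- stats::predict(fit, data = mf[na_idx[[v]], , drop = FALSE],
                             num.threads = 1)$predictions
      if (v %in% to_factor) {
        pred <- as.character(pred)
        if (types[[v]] == "binary") pred <- as.numeric(pred)
      }
      work[[v]][na_idx[[v]]] <- pred
      oob[v] <- fit$prediction.error  # MSE (regression) or misclassification
      if (!v %in% to_factor) {
        vy <- stats::var(ydat[[v]])
        oob[v] <- if (vy > 0) sqrt(oob[v] / vy) else sqrt(oob[v])
      }
    }
    d_num <- if (length(numeric_targets)) {
      num <- den <- 0
      for (v in numeric_targets) {
        idx <- na_idx[[v]]
        num <- num + sum((work[[v]][idx] - old[[v]][idx])^2)
        den <- den + sum(work[[v]][idx]^2)
      }
      if (den > 0) num / den else 0
    } else 0
    d_cat <- if (length(cat_targets)) {
      chg <- tot <- 0
      for (v in cat_targets) {
        idx <- na_idx[[v]]
        chg <- chg + sum(work[[v]][idx] != old[[v]][idx])
        tot <- tot + length(idx)
      }
      chg / tot
    } else 0
    trace <- rbind(trace, data.frame(iteration = iter, delta_numeric = d_num,
                                     delta_categorical = d_cat))
    if (d_num > prev$d_num || d_cat > prev$d_cat) {
      work <- old  # return the sweep before the increase
      iter <- iter - 1L
      break
    }
    prev <- list(d_num = d_num, d_cat = d_cat)
  }

  completed <- table
  for (v in targets) completed[[v]][na_idx[[v]]] <- work[[v]][na_idx[[v]]]
  structure(list(table = completed, iterations = max(iter, 1L),
                 oob_error = oob, trace = trace),
            class = "graftnet_imputation")
}

#' Imputation quality against known truth
#'
#' NRMSE over masked numeric cells, `sqrt(mean((imp - true)^2) / var(true))`,
#' and the proportion of falsely classified masked categorical cells (PFC).
#'
#' @param truth Complete reference table.
#' @param imputed Completed table from an imputation method.
#' @param mask Named list mapping variable names to the row indices that were
#'   masked.
#' @return List with `nrmse` and `pfc` (either may be `NA` when no cell of
#'   that kind was masked; an entirely empty mask is an error).
#' @export
imputation_quality <- function(truth, imputed, mask) {
  mask <- mask[vapply(mask, length, integer(1)) > 0]
  if (!length(mask)) stop("empty mask: no imputed cells to score", call. = FALSE)
  types <- impute_var_types(truth)
  sq <- tv <- c()
  n_cat <- n_wrong <- 0
  for (v in names(mask)) {
    idx <- mask[[v]]
    if (types[[v]] %in% c("binary", "category")) {
      n_cat <- n_cat + length(idx)
      n_wrong <- n_wrong + sum(truth[[v]][idx] != imputed[[v]][idx])
    } else {
      sq <- c(sq, (imputed[[v]][idx] - truth[[v]][idx])^2)
      tv <- c(tv, truth[[v]][idx])
    }
  }
  list(nrmse = if (length(sq)) sqrt(mean(sq) / stats::var(tv)) else NA_real_,
       pfc = if (n_cat) n_wrong / n_cat else NA_real_)
}
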