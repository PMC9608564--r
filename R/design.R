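#' Candidate predictor columns
#'
#' Names and metadata of the 25 candidate design-matrix columns: the raw
#' covariates, ESRD-cause dummies (reference level `other`), recipient maximum
#' PRA both as an integer and as a strict `> 50` indicator, natural-log
#' transformations `ln(years on dialysis + 1)` and `ln(weight + 1)`, and the
#' recipient-age hinge `max(age - 50, 0)`.
#'
#' @return Data frame with columns `name`, `type` and `transform`.
#' @export
design_columns <- function() {
  data.frame(
    name = c("recipient_age", "recipient_age_over_50",
             "recipient_weight", "recipient_ln_weight",
             "recipient_years_dialysis", "recipient_ln_years_dialysis",
             "recipient_male", "recipient_prev_transplant",
             "recipient_hypertension", "recipient_diabetes", "recipient_pvd",
             "recipient_max_pra", "recipient_pra_gt_50",
             "esrd_glomerulopathies", "esrd_diabetes", "esrd_hypertension",
             "donor_age", "donor_male", "donor_living", "donor_hypertension",
             "donor_diabetes", "donor_creatinine_gt_1_5", "donor_death_cva",
             "cold_ischemia_hours", "hla_mismatch"),
    type = c("integer", "integer", "numeric", "numeric", "numeric", "numeric",
             "binary", "binary", "binary", "binary", "binary",
             "integer", "binary", "binary", "binary", "binary",
             "integer", "binary", "binary", "binary", "binary", "binary",
             "binary", "numeric", "integer"),
    transform = c("identity", "hinge_50", "identity", "log1p", "identity",
                  "log1p", rep("identity", 6), "gt_50", rep("dummy", 3),
                  rep("identity", 9))
  )
}

#' Build the candidate design matrix
#'
#' Expands a complete (post-imputation) cohort table into the 25 candidate
#' predictor columns described by [design_columns()]. All logs are natural
#' logs; the PRA indicator is strictly greater than 50; `transplant_year` is
#' not a candidate predictor.
#'
#' @param table Complete cohort data frame.
#' @return Numeric matrix with 25 named columns and attribute `design_info`
#'   (the [design_columns()] metadata).
#' @export
build_design_matrix <- function(table) {
  covars <- cohort_schema()
  covars <- setdiff(covars$name[covars$role == "covariate"], "transplant_year")
  incomplete <- covars[vapply(covars, function(v) anyNA(table[[v]]), logical(1))]
  if (length(incomplete))
    stop("missing values in ", paste(incomplete, collapse = ", "),
         "; impute the cohort (see missforest_impute) before building the ",
         "design matrix", call. = FALSE)
  X <- cbind(
    recipient_age = table$recipient_age,
    recipient_age_over_50 = pmax(table$recipient_age - 50, 0),
    recipient_weight = table$recipient_weight,
    recipient_ln_weight = log(table$recipient_weight + 1),
    recipient_years_dialysis = table$recipient_years_dialysis,
    recipient_ln_years_dialysis = log(table$recipient_years_dialysis + 1),
    recipient_male = table$recipient_male,
    recipient_prev_transplant = table$recipient_prev_transplant,
    recipient_hypertension = table$recipient_hypertension,
    recipient_diabetes = table$recipient_diabetes,
    recipient_pvd = table$recipient_pvd,
    recipient_max_pra = table$recipient_max_pra,
    recipient_pra_gt_50 = as.numeric(table$recipient_max_pra > 50),
    esrd_glomerulopathies = as.numeric(table$recipient_esrd_cause == "glomerulopathies"),
    esrd_diabetes = as.numeric(table$recipient_esrd_cause == "diabetes"),
    esrd_hypertension = as.numeric(table$recipient_esrd_cause == "hypertension"),
    donor_age = table$donor_age,
    donor_male = table$donor_male,
    donor_living = table$donor_living,
    donor_hypertension = table$donor_hypertension,
    donor_diabetes = table$donor_diabetes,
    donor_creatinine_gt_1_5 = table$donor_creatinine_gt_1_5,
    donor_death_cva = table$donor_death_cva,
    cold_ischemia_hours = table$cold_ischemia_hours,
    hla_mismatch = table$hla_mismatch
  )
  attr(X, "design_info") <- design_columns()
  X
}
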