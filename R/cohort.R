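#' Cohort schema
#'
#' Column definitions for a per-transplant cohort table: donor, recipient and
#' transplant covariates, the follow-up time in years and a three-state outcome
#' (`graft_failure`, `death_functioning`, `censored`). Any covariate may be
#' missing (`NA`); `followup_time` and `outcome` may not.
#'
#' @return A data frame with one row per column of the cohort schema and fields
#'   `name`, `type` (`numeric`, `binary`, `integer`, `category`) and `role`
#'   (`covariate` or `outcome`).
#' @export
cohort_schema <- function() {
  rbind(
    data.frame(name = c("recipient_age", "recipient_weight",
                        "recipient_years_dialysis", "cold_ischemia_hours"),
               type = "numeric", role = "covariate"),
    data.frame(name = c("recipient_male", "recipient_prev_transplant",
                        "recipient_hypertension", "recipient_diabetes",
                        "recipient_pvd", "donor_male", "donor_living",
                        "donor_hypertension", "donor_diabetes",
                        "donor_creatinine_gt_1_5", "donor_death_cva"),
               type = "binary", role = "covariate"),
    data.frame(name = c("recipient_max_pra", "donor_age", "hla_mismatch",
                        "transplant_year"),
               type = "integer", role = "covariate"),
    data.frame(name = "recipient_esrd_cause", type = "category",
               role = "covariate"),
    data.frame(name = "followup_time", type = "numeric", role = "outcome"),
    data.frame(name = "outcome", type = "category", role = "outcome")
  )
}

esrd_levels <- function() c("glomerulopathies", "diabetes", "hypertension", "other")
outcome_levels <- function() c("graft_failure", "death_functioning", "censored")

#' Read a cohort table from CSV
#'
#' Header names are matched case-insensitively against [cohort_schema()].
#' Unparseable or out-of-range cells in covariates become missing (`NA`) with a
#' warning; an unparseable `followup_time` or `outcome` is an error, as is a
#' missing `followup_time`/`outcome` column or an empty file.
#'
#' @param path Path to a CSV file with one row per transplant.
#' @return A data frame with the schema's columns (missing covariate columns are
#'   created as all-`NA`).
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  if (nrow(raw) == 0L) stop("empty cohort file: ", path, call. = FALSE)
  names(raw) <- tolower(trimws(names(raw)))
  sch <- cohort_schema()
  missing_mandatory <- setdiff(c("followup_time", "outcome"), names(raw))
  if (length(missing_mandatory))
    stop("cohort CSV lacks mandatory column(s): ",
         paste(missing_mandatory, collapse = ", "), call. = FALSE)

  out <- data.frame(row.names = seq_len(nrow(raw)))
  for (k in seq_len(nrow(sch))) {
    nm <- sch$name[k]
    if (!nm %in% names(raw)) {
      out[[nm]] <- if (sch$type[k] == "category") NA_character_ else NA_real_
      next
    }
    cell <- trimws(raw[[nm]])
    cell[cell %in% c("", "NA", "na", "NaN")] <- NA
    if (sch$type[k] == "category" && nm != "outcome") {
      val <- tolower(cell)
      bad <- !is.na(val) & !val %in% esrd_levels()
      if (any(bad)) {
        warning(sum(bad), " unparseable value(s) in ", nm, " set to missing")
        val[bad] <- NA
      }
      out[[nm]] <- val
    } else if (nm == "outcome") {
      val <- tolower(cell)
      if (anyNA(val) || !all(val %in% outcome_levels()))
        stop("unparseable or missing `outcome` value(s); expected one of ",
             paste(outcome_levels(), collapse = ", "), call. = FALSE)
      out[[nm]] <- val
    } else if (nm == "followup_time") {
      val <- suppressWarnings(as.numeric(cell))
      if (anyNA(val)) stop("unparseable or missing `followup_time` value(s)",
                           call. = FALSE)
      out[[nm]] <- val
    } else {
      val <- suppressWarnings(as.numeric(cell))
      bad <- !is.na(cell) & is.na(val)
      if (sch$type[k] == "binary") bad <- bad | (!is.na(val) & !val %in% c(0, 1))
      if (nm == "recipient_max_pra") bad <- bad | (!is.na(val) & (val < 0 | val > 100))
      if (nm == "hla_mismatch") bad <- bad | (!is.na(val) & !val %in% 0:6)
      if (any(bad)) {
        warning(sum(bad), " unparseable/out-of-range value(s) in ", nm,
                " set to missing")
        val[bad] <- NA
      }
      out[[nm]] <- val
    }
  }
  out
}

#' Write a cohort table to CSV
#'
#' Missing cells are written as `NA`; [read_cohort()] round-trips them.
#'
#' @param table Cohort data frame.
#' @param path Output CSV path.
#' @export
write_cohort <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Apply the cohort inclusion filters
#'
#' Reproduces the four-step sample-selection sequence used when assembling an
#' adult transplant cohort: (1) transplant year within the study window;
#' (2) record consistency (`followup_time > 0`, dialysis years non-negative and
#' not exceeding recipient age); (3) complete data on the non-imputable set
#' (follow-up time, outcome, HLA mismatch, ESRD cause and the recipient
#' comorbidity flags); (4) adult donor and recipient. The order matters because
#' removal counts are attributed to the first failing step; the default order
#' matches the sequence above but can be permuted.
#'
#' @param table Cohort data frame.
#' @param window Length-2 numeric, inclusive transplant-year window.
#' @param adult_age Minimum donor and recipient age in years.
#' @param order Character vector permuting
#'   `c("window", "consistency", "missing", "pediatric")`.
#' @return A list with `table` (surviving records) and `log`, a data frame with
#'   one row per step: `filter`, `removed`, `remaining`.
#' @export
apply_inclusion_filters <- function(table, window = c(1998, 2018),
                                    adult_age = 18,
                                    order = c("window", "consistency",
                                              "missing", "pediatric")) {
  if (nrow(table) == 0L) stop("empty cohort table", call. = FALSE)
  if (length(window) != 2L || window[1] > window[2])
    stop("invalid year window: min > max", call. = FALSE)
  order <- match.arg(order, several.ok = TRUE)
  if (length(order) != 4L) stop("`order` must permute all four filters",
                                call. = FALSE)
  nonimputable <- c("followup_time", "outcome", "hla_mismatch",
                    "recipient_esrd_cause", "recipient_hypertension",
                    "recipient_diabetes", "recipient_pvd")
  keep_fun <- list(
    window = function(d) !is.na(d$transplant_year) &
      d$transplant_year >= window[1] & d$transplant_year <= window[2],
    consistency = function(d) d$followup_time > 0 &
      !(!is.na(d$recipient_years_dialysis) &
          (d$recipient_years_dialysis < 0 |
             (!is.na(d$recipient_age) &
                d$recipient_years_dialysis > d$recipient_age))),
    missing = function(d) stats::complete.cases(d[, nonimputable, drop = FALSE]),
    pediatric = function(d) (is.na(d$donor_age) | d$donor_age >= adult_age) &
      (is.na(d$recipient_age) | d$recipient_age >= adult_age)
  )
  log <- data.frame(filter = character(0), removed = integer(0),
                    remaining = integer(0))
  for (step in order) {
    keep <- keep_fun[[step]](table)
    removed <- sum(!keep)
    table <- table[keep, , drop = FALSE]
    log <- rbind(log, data.frame(filter = step, removed = removed,
                                 remaining = nrow(table)))
  }
  rownames(table) <- NULL
  list(table = table, log = log)
}

#' Code the survival outcome
#'
#' In death-censored mode (the primary analysis) graft failure is the event and
#' death with a functioning graft is censored at the time of death, equivalent
#' to a last follow-up with a functioning graft. In `overall` mode death with a
#' functioning graft also counts as an event.
#'
#' @param table Cohort data frame with `followup_time` and `outcome`.
#' @param mode `"death_censored"` (default) or `"overall"`.
#' @return A data frame with columns `time` and `event` (0/1).
#' @export
to_death_censored <- function(table, mode = c("death_censored", "overall")) {
  mode <- match.arg(mode)
  if (anyNA(table$followup_time) || anyNA(table$outcome))
    stop("`followup_time` and `outcome` must be complete", call. = FALSE)
  event_states <- if (mode == "overall")
    c("graft_failure", "death_functioning") else "graft_failure"
  out <- data.frame(time = table$followup_time,
                    event = as.integer(table$outcome %in% event_states))
  check_outcomes(out)
}

#' Descriptive cohort summary
#'
#' Mean (SD) for numeric variables and n (%) per level for binary/categorical
#' variables, with the event count per level when outcomes are supplied, plus
#' the percentage of missing cells per variable.
#'
#' @param table Cohort data frame.
#' @param outcomes Optional `(time, event)` data frame aligned with `table`.
#' @return A long data frame with one row per variable (numerics) or per level
#'   (categoricals).
#' @export
summarize_cohort <- function(table, outcomes = NULL) {
  sch <- cohort_schema()
  sch <- sch[sch$role == "covariate", ]
  n <- nrow(table)
  ev <- if (!is.null(outcomes)) outcomes$event else NULL
  rows <- list()
  for (k in seq_len(nrow(sch))) {
    nm <- sch$name[k]
    x <- table[[nm]]
    miss_pct <- 100 * mean(is.na(x))
    if (sch$type[k] %in% c("numeric", "integer") &&
        !nm %in% c("hla_mismatch")) {
      rows[[length(rows) + 1L]] <- data.frame(
        variable = nm, level = NA_character_,
        mean = mean(x, na.rm = TRUE), sd = stats::sd(x, na.rm = TRUE),
        n = sum(!is.na(x)), pct = NA_real_, events = NA_real_,
        missing_pct = miss_pct)
    } else {
      lev <- sort(unique(x[!is.na(x)]))
      for (l in lev) {
        sel <- !is.na(x) & x == l
        rows[[length(rows) + 1L]] <- data.frame(
          variable = nm, level = as.character(l),
          mean = NA_real_, sd = NA_real_,
          n = sum(sel), pct = 100 * sum(sel) / sum(!is.na(x)),
          events = if (is.null(ev)) NA_real_ else sum(ev[sel]),
          missing_pct = miss_pct)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
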