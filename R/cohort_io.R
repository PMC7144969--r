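#' Default cohort CSV schema
#'
#' Maps the canonical participant fields to column names in a cohort CSV and
#' declares the cholesterol unit. The default dialect is
#' `id,age,sex,sbp,tc,hdl,smoker,diabetes,antihtn,prior_mi,fu_years,status,cause`
#' with booleans coded 0/1, sex as `M`/`F`, status as `0` (alive/censored) /
#' `1` (dead) and cause of death as `CV`/`NONCV`/`UNK`/`NA`.
#'
#' @param chol_unit Unit of the cholesterol columns, `"mmol_l"` or `"mg_dl"`.
#'   Values in mg/dl are converted to mmol/l on read by dividing by 38.67.
#' @param ... Overrides of individual field-to-column mappings, e.g.
#'   `sbp = "sys_bp"`.
#' @return A named list of class `"cohort_schema"`.
#' @export
cohort_schema <- function(chol_unit = c("mmol_l", "mg_dl"), ...) {
  chol_unit <- match.arg(chol_unit)
  schema <- list(
    id = "id", age = "age", sex = "sex", sbp = "sbp",
    total_chol = "tc", hdl_chol = "hdl", smoker = "smoker",
    diabetes = "diabetes", antihypertensive = "antihtn",
    prior_mi = "prior_mi", followup_years = "fu_years",
    status = "status", death_cause = "cause"
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(schema))
  if (length(bad)) stop("unknown schema field(s): ", paste(bad, collapse = ", "))
  schema[names(dots)] <- dots
  schema$chol_unit <- chol_unit
  class(schema) <- "cohort_schema"
  schema
}

#' mg/dl to mmol/l conversion factor for cholesterol
#' @keywords internal
MGDL_PER_MMOLL <- 38.67

CAUSE_LEVELS <- c("cv", "non_cv", "unknown", "not_applicable")

new_cohort <- function(df, provenance = NULL) {
  if (is.null(provenance)) {
    provenance <- data.frame(step = character(), excluded = integer(),
                             stringsAsFactors = FALSE)
  }
  structure(df, provenance = provenance, class = c("cohort", "data.frame"))
}

#' @export
print.cohort <- function(x, ...) {
  cat("Cohort of", nrow(x), "participants\n")
  prov <- attr(x, "provenance")
  if (nrow(prov)) {
    cat("Exclusion flow:\n")
    for (i in seq_len(nrow(prov)))
      cat(sprintf("  %-28s -%d\n", prov$step[i], prov$excluded[i]))
  }
  NextMethod()
  invisible(x)
}

#' Exclusion-flow provenance of a cohort
#'
#' @param cohort A `cohort` object.
#' @return Data frame with one row per applied filter (`step`, `excluded`).
#' @export
cohort_provenance <- function(cohort) attr(cohort, "provenance")

parse_bool <- function(x, field, id) {
  out <- rep(NA, length(x))
  x_chr <- trimws(toupper(as.character(x)))
  out[x_chr %in% c("1", "TRUE", "T", "YES", "Y")] <- TRUE
  out[x_chr %in% c("0", "FALSE", "F", "NO", "N")] <- FALSE
  bad <- !is.na(x_chr) & x_chr != "" & x_chr != "NA" & is.na(out)
  if (any(bad))
    stop(sprintf("unparseable value for field '%s' in record(s): %s",
                 field, paste(id[bad], collapse = ", ")))
  out
}

parse_num <- function(x, field, id) {
  out <- suppressWarnings(as.numeric(x))
  x_chr <- trimws(as.character(x))
  bad <- !is.na(x_chr) & x_chr != "" & x_chr != "NA" & is.na(out)
  if (any(bad))
    stop(sprintf("unparseable numeric value for field '%s' in record(s): %s",
                 field, paste(id[bad], collapse = ", ")))
  out
}

#' Read a participant-level cohort CSV
#'
#' Parses baseline risk factors and follow-up outcome fields, normalises
#' cholesterol to mmol/l when the schema declares mg/dl, and preserves missing
#' values as `NA` without imputation or filtering. Validation of plausibility
#' windows happens here; inclusion filtering is a separate, explicit step
#' ([apply_inclusion()]).
#'
#' @param path Path to a CSV file with a header row.
#' @param schema A [cohort_schema()].
#' @param age_window Plausible age window (years); ages outside it raise an
#'   error. Defaults to 18-110.
#' @return A `cohort` object: a data frame with canonical columns `id`, `age`,
#'   `sex` (`"male"`/`"female"`), `sbp` (mmHg), `total_chol` and `hdl_chol`
#'   (mmol/l), `smoker`, `diabetes`, `antihypertensive` (logical), `prior_mi`
#'   (`"yes"`/`"no"`/`NA`), `followup_years`, `status`
#'   (`"alive_censored"`/`"dead"`), `death_cause`
#'   (`"cv"`/`"non_cv"`/`"unknown"`/`"not_applicable"`), plus a provenance
#'   attribute recording exclusion steps.
#' @export
read_cohort <- function(path, schema = cohort_schema(), age_window = c(18, 110)) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  fields <- setdiff(names(schema), "chol_unit")
  cols <- unlist(schema[fields])
  missing_cols <- cols[!cols %in% names(raw)]
  if (length(missing_cols))
    stop("cohort file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  as_cohort_df(stats::setNames(raw[cols], fields),
               chol_unit = schema$chol_unit, age_window = age_window)
}

as_cohort_df <- function(df, chol_unit = "mmol_l", age_window = c(18, 110)) {
  id <- as.character(df$id)
  if (anyDuplicated(id))
    stop("duplicated participant id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  out <- data.frame(id = id, stringsAsFactors = FALSE)
  out$age <- parse_num(df$age, "age", id)
  sex <- trimws(tolower(as.character(df$sex)))
  sex[sex %in% c("m", "male")] <- "male"
  sex[sex %in% c("f", "female")] <- "female"
  if (any(!is.na(sex) & !sex %in% c("male", "female")))
    stop("unparseable sex value(s)")
  out$sex <- sex
  out$sbp <- parse_num(df$sbp, "sbp", id)
  out$total_chol <- parse_num(df$total_chol, "total_chol", id)
  out$hdl_chol <- parse_num(df$hdl_chol, "hdl_chol", id)
  if (chol_unit == "mg_dl") {
    out$total_chol <- out$total_chol / MGDL_PER_MMOLL
    out$hdl_chol <- out$hdl_chol / MGDL_PER_MMOLL
  }
  out$smoker <- parse_bool(df$smoker, "smoker", id)
  out$diabetes <- parse_bool(df$diabetes, "diabetes", id)
  out$antihypertensive <- parse_bool(df$antihypertensive, "antihypertensive", id)
  pm <- trimws(tolower(as.character(df$prior_mi)))
  pm[pm %in% c("1", "true", "yes", "y")] <- "yes"
  pm[pm %in% c("0", "false", "no", "n")] <- "no"
  pm[pm %in% c("", "na")] <- NA
  if (any(!is.na(pm) & !pm %in% c("yes", "no")))
    stop("unparseable prior_mi value(s)")
  out$prior_mi <- pm
  out$followup_years <- parse_num(df$followup_years, "followup_years", id)
  st <- trimws(tolower(as.character(df$status)))
  st[st %in% c("0", "alive", "censored", "alive_censored")] <- "alive_censored"
  st[st %in% c("1", "dead", "died")] <- "dead"
  if (any(!is.na(st) & !st %in% c("alive_censored", "dead")))
    stop("unparseable status value(s)")
  out$status <- st
  cause <- trimws(toupper(as.character(df$death_cause)))
  cause_map <- c(CV = "cv", NONCV = "non_cv", NON_CV = "non_cv",
                 UNK = "unknown", UNKNOWN = "unknown", "NA" = "not_applicable")
  cause[is.na(cause) | cause == ""] <- "NA"
  if (any(!cause %in% names(cause_map)))
    stop("unparseable cause value(s)")
  out$death_cause <- unname(cause_map[cause])
  validate_cohort_values(out, age_window)
  new_cohort(out)
}

validate_cohort_values <- function(df, age_window) {
  chk <- function(bad, msg) {
    bad <- which(bad)
    if (length(bad))
      stop(msg, " (record(s): ", paste(df$id[utils::head(bad, 5)], collapse = ", "), ")")
  }
  chk(!is.na(df$age) & (df$age < age_window[1] | df$age > age_window[2]),
      sprintf("age outside plausible window [%g, %g]", age_window[1], age_window[2]))
  chk(!is.na(df$followup_years) & df$followup_years < 0, "negative follow-up")
  chk(!is.na(df$total_chol) & df$total_chol <= 0, "non-positive total cholesterol")
  chk(!is.na(df$hdl_chol) & df$hdl_chol <= 0, "non-positive HDL cholesterol")
  chk(!is.na(df$total_chol) & !is.na(df$hdl_chol) & df$hdl_chol >= df$total_chol,
      "HDL cholesterol not below total cholesterol")
  chk(!is.na(df$status) & df$status == "alive_censored" &
        df$death_cause != "not_applicable",
      "death cause recorded for a censored participant")
  chk(!is.na(df$status) & df$status == "dead" &
        df$death_cause == "not_applicable",
      "dead participant without a cause class (use UNK if unknown)")
  invisible(df)
}

#' Write a cohort back to CSV (plus optional exclusion-flow JSON)
#'
#' Serialises in the default dialect so that `read_cohort(write_cohort(x))`
#' round-trips values exactly. Hidden audit columns from the synthetic
#' generator are dropped unless `debug = TRUE`.
#'
#' @param cohort A `cohort`.
#' @param path Output CSV path.
#' @param flow_path Optional path for a JSON log of the exclusion flow.
#' @param debug If `TRUE`, audit columns (names starting with `.`) are kept.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, flow_path = NULL, debug = FALSE) {
  df <- as.data.frame(cohort)
  if (!debug) df <- df[, !startsWith(names(df), "."), drop = FALSE]
  out <- data.frame(
    id = df$id, age = df$age,
    sex = c(male = "M", female = "F")[df$sex],
    sbp = df$sbp, tc = df$total_chol, hdl = df$hdl_chol,
    smoker = as.integer(df$smoker), diabetes = as.integer(df$diabetes),
    antihtn = as.integer(df$antihypertensive),
    prior_mi = df$prior_mi, fu_years = df$followup_years,
    status = ifelse(df$status == "dead", 1L, 0L),
    cause = c(cv = "CV", non_cv = "NONCV", unknown = "UNK",
              not_applicable = "NA")[df$death_cause],
    stringsAsFactors = FALSE
  )
  audit <- names(df)[startsWith(names(df), ".")]
  if (debug && length(audit)) out <- cbind(out, df[audit])
  utils::write.csv(out, path, row.names = FALSE, na = "")
  if (!is.null(flow_path)) {
    prov <- attr(cohort, "provenance")
    jsonlite::write_json(
      list(input_n = nrow(cohort) + sum(prov$excluded),
           steps = prov, final_n = nrow(cohort)),
      flow_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Derive diabetes status from medication use and HbA1c
#'
#' Diabetes is defined as self-reported use of antidiabetic medication and/or
#' a measured HbA1c level strictly above 6.5%. Either input may be missing:
#' the result is `TRUE` as soon as one criterion is established, `FALSE` only
#' when both are known negative, `NA` otherwise.
#'
#' @param med_flag Logical (vector): antidiabetic medication use.
#' @param hba1c Numeric (vector): HbA1c in percent; must lie in (0, 25).
#' @return Logical vector.
#' @export
derive_diabetes <- function(med_flag, hba1c) {
  n <- max(length(med_flag), length(hba1c))
  med_flag <- rep_len(as.logical(med_flag), n)
  hba1c <- rep_len(as.numeric(hba1c), n)
  if (any(!is.na(hba1c) & (hba1c <= 0 | hba1c >= 25)))
    stop("HbA1c outside the plausible range (0, 25)%")
  high <- hba1c > 6.5
  out <- med_flag | high           # NA-propagating OR: TRUE | NA is TRUE
  out
}

#' Apply the inclusion criteria of the validation analysis
#'
#' Removes, in this order: participants with a self-reported or missing prior
#' myocardial infarction; participants missing any required risk factor
#' (complete-case policy); participants without any follow-up. A record
#' failing several criteria is counted at the first, as in a flow diagram.
#' The exclusion counts are appended to the cohort's provenance.
#'
#' @param cohort A `cohort`.
#' @param required_fields Fields that must be non-missing; defaults to the
#'   union of fields used by the SCORE and SCORE OP equations.
#' @return The filtered `cohort`.
#' @export
apply_inclusion <- function(cohort,
                            required_fields = c("age", "sex", "sbp",
                                                "total_chol", "hdl_chol",
                                                "smoker", "diabetes")) {
  df <- as.data.frame(cohort)
  prov <- attr(cohort, "provenance")

  excl_mi <- is.na(df$prior_mi) | df$prior_mi == "yes"
  miss_rf <- Reduce(`|`, lapply(df[required_fields], is.na))
  no_fu <- (is.na(df$followup_years) |
              (df$followup_years == 0 &
                 (is.na(df$status) | df$status == "alive_censored")))

  miss_rf <- miss_rf & !excl_mi
  no_fu <- no_fu & !excl_mi & !miss_rf

  prov <- rbind(prov, data.frame(
    step = c("prior MI (reported or missing)",
             "missing risk factor(s)",
             "no follow-up"),
    excluded = c(sum(excl_mi), sum(miss_rf), sum(no_fu)),
    stringsAsFactors = FALSE))

  keep <- !(excl_mi | miss_rf | no_fu)
  if (!any(keep)) warning("all records excluded; cohort is empty")
  new_cohort(df[keep, , drop = FALSE], prov)
}

#' Total person-years of follow-up
#'
#' @param cohort A `cohort` with `followup_years` present for all records.
#' @return Sum of follow-up years.
#' @export
person_years <- function(cohort) {
  fu <- cohort$followup_years
  if (any(is.na(fu))) stop("followup_years missing for some records")
  if (any(fu < 0)) stop("negative follow-up")
  sum(fu)
}

#' Follow-up years from calendar dates
#'
#' Returns the years from recruitment to the earliest applicable endpoint:
#' the death date if it precedes administrative censorship, otherwise the
#' last-visit date (loss to follow-up) or the administrative censorship date,
#' whichever applies first. A death after the administrative date counts as
#' censored alive at that date.
#'
#' @param recruit_date,event_date,last_visit_date,admin_date `Date` vectors
#'   (scalars recycled); `event_date` and `last_visit_date` may be `NA`.
#' @return Numeric vector of follow-up years (365.25-day years).
#' @export
followup_from_dates <- function(recruit_date, event_date = NA,
                                last_visit_date = NA, admin_date) {
  n <- max(length(recruit_date), length(event_date),
           length(last_visit_date), length(admin_date))
  recruit_date <- rep_len(as.Date(recruit_date), n)
  event_date <- rep_len(as.Date(event_date), n)
  last_visit_date <- rep_len(as.Date(last_visit_date), n)
  admin_date <- rep_len(as.Date(admin_date), n)

  end <- admin_date
  lost <- !is.na(last_visit_date) & last_visit_date < end
  end[lost] <- last_visit_date[lost]
  died <- !is.na(event_date) & event_date <= end
  end[died] <- event_date[died]

  yrs <- as.numeric(end - recruit_date) / 365.25
  if (any(yrs < 0)) stop("endpoint precedes recruitment")
  yrs
}
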