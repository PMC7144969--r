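#' Validate one vector of predicted risks against cohort follow-up
#'
#' The per-equation core of the validation pipeline: decile grouping,
#' calibration table ("actual" probabilities from group-wise Kaplan-Meier
#' within observed follow-up, or from grouped Weibull regression projection
#' beyond it), calibration-in-the-large, the Nam-D'Agostino chi-square, and
#' Harrell's C on the entire observed follow-up with a BCa bootstrap
#' interval.
#'
#' @param cohort A `cohort` that passed [apply_inclusion()].
#' @param risks Predicted risks aligned with the cohort rows.
#' @param horizon Horizon in years of the risks.
#' @param name Label for the report.
#' @param actual_source `"km"` or `"weibull"`; default `"auto"` picks
#'   Kaplan-Meier when the horizon lies within observed follow-up and the
#'   Weibull projection otherwise.
#' @param G Number of risk groups (default 10 deciles).
#' @param B Bootstrap replicates for the C-index interval (0 skips it).
#' @param B_calibration Bootstrap replicates for Weibull projection
#'   intervals in the calibration table (0 skips them; they are plot
#'   uncertainty only).
#' @param seed Integer seed for all bootstrap draws.
#' @param conf Confidence level.
#' @return List of class `validation_report`: `name`, `horizon`,
#'   `actual_source`, `calibration` (the table), `predicted_events`,
#'   `actual_events`, `ratio`, `chi_square`, `df`, `p_value`, `c_index`,
#'   `c_ci_lower`, `c_ci_upper`, `B`, `seed`.
#' @export
validate_risks <- function(cohort, risks, horizon, name = "risk score",
                           actual_source = c("auto", "km", "weibull"),
                           G = 10, B = 2000, B_calibration = 0,
                           seed = 1, conf = 0.95) {
  actual_source <- match.arg(actual_source)
  times <- cohort$followup_years
  events <- cv_events(cohort)
  if (actual_source == "auto")
    actual_source <- if (horizon <= max(times)) "km" else "weibull"
  assign <- decile_groups(risks, G)
  tab <- calibration_table(assign, risks, times, events, horizon,
                           actual_source = actual_source,
                           B = B_calibration, seed = seed, conf = conf)
  totals <- expected_and_actual_events(tab)
  nd <- nam_dagostino(tab)
  cstat <- harrell_c(times, events, risks)
  c_lo <- c_hi <- NA_real_
  if (B > 0) {
    dat <- data.frame(t = times, e = events, r = risks)
    bb <- bca_bootstrap(
      dat, function(d) harrell_c(d$t, d$e, d$r), B = B, seed = seed,
      conf = conf, jackknife_values = harrell_c_jackknife(times, events, risks))
    c_lo <- bb$ci_lower; c_hi <- bb$ci_upper
  }
  structure(list(name = name, horizon = horizon,
                 actual_source = actual_source, calibration = tab,
                 predicted_events = totals$predicted_events,
                 actual_events = totals$actual_events, ratio = totals$ratio,
                 chi_square = nd$chi_square, df = nd$df, p_value = nd$p_value,
                 c_index = cstat, c_ci_lower = c_lo, c_ci_upper = c_hi,
                 B = B, seed = seed),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %s (%g-year horizon, actuals: %s)\n",
              x$name, x$horizon, x$actual_source))
  cat(sprintf("  predicted/actual events: %d / %d (ratio %.2f)\n",
              x$predicted_events, x$actual_events, x$ratio))
  cat(sprintf("  Nam-D'Agostino chi-square: %.2f on %d df (p %s)\n",
              x$chi_square, x$df,
              ifelse(x$p_value < 0.001, "< 0.001",
                     sprintf("= %.3f", x$p_value))))
  if (is.na(x$c_ci_lower)) {
    cat(sprintf("  C-index: %.2f\n", x$c_index))
  } else {
    cat(sprintf("  C-index: %.2f (%.2f to %.2f)\n",
                x$c_index, x$c_ci_lower, x$c_ci_upper))
  }
  invisible(x)
}

#' Run the full external validation for a set of equations
#'
#' For every requested equation: compute predicted risks on the cohort, then
#' delegate to [validate_risks()] with the equation's horizon (5-year
#' equations are assessed against Kaplan-Meier actuals within observed
#' follow-up; 10-year equations against Weibull-projected actuals). Pure
#' function of (cohort, registry, config, seed).
#'
#' @param cohort A `cohort` that passed [apply_inclusion()].
#' @param registry Named list of `risk_equation`s (see
#'   [default_equation_registry()]).
#' @param equations Equation names to validate, or `"all"`.
#' @param G,B,B_calibration,seed,conf Passed to [validate_risks()].
#' @return Named list of `validation_report`s, with the predicted-risk
#'   vectors attached as attribute `"risks"`; `as.data.frame()` turns it
#'   into the summary table of measures of validity.
#' @export
run_validation <- function(cohort, registry = default_equation_registry(),
                           equations = "all", G = 10, B = 2000,
                           B_calibration = 0, seed = 1, conf = 0.95) {
  if (identical(equations, "all")) equations <- names(registry)
  missing_eq <- setdiff(equations, names(registry))
  if (length(missing_eq))
    stop("equation(s) not in registry: ", paste(missing_eq, collapse = ", "))
  risks <- lapply(registry[equations],
                  function(eq) suppressWarnings(predict_cohort(cohort, eq)))
  reports <- lapply(equations, function(nm)
    validate_risks(cohort, risks[[nm]], horizon = registry[[nm]]$horizon,
                   name = nm, G = G, B = B, B_calibration = B_calibration,
                   seed = seed, conf = conf))
  names(reports) <- equations
  structure(reports, risks = risks, class = "validation_report_set")
}

#' @export
as.data.frame.validation_report_set <- function(x, ...) {
  do.call(rbind, lapply(unname(x), function(r)
    data.frame(equation = r$name, horizon = r$horizon,
               actual_source = r$actual_source,
               predicted = r$predicted_events, actual = r$actual_events,
               ratio = r$ratio, chi_square = r$chi_square, df = r$df,
               p_value = r$p_value, c_index = r$c_index,
               c_ci_lower = r$c_ci_lower, c_ci_upper = r$c_ci_upper,
               stringsAsFactors = FALSE)))
}

#' @export
print.validation_report_set <- function(x, ...) {
  for (r in x) { print(r); cat("\n") }
  invisible(x)
}

#' Serialize a validation report set
#'
#' Writes the summary table as CSV and, optionally, the full report
#' (including per-decile calibration tables and the run seed) as JSON.
#'
#' @param reports A `validation_report_set`.
#' @param csv_path Path for the summary CSV.
#' @param json_path Optional path for the JSON report.
#' @return `csv_path`, invisibly.
#' @export
write_validation_report <- function(reports, csv_path, json_path = NULL) {
  utils::write.csv(as.data.frame(reports), csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    payload <- lapply(reports, function(r) {
      r$calibration <- as.data.frame(r$calibration)
      unclass(r)
    })
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(csv_path)
}

#' Very-high-risk threshold classification
#'
#' Percentage of the cohort whose predicted 10-year risk meets or exceeds
#' each hypothetical very-high-risk threshold, per equation, plus a
#' reference row from a full-covariate Weibull model's projected 10-year
#' probabilities (the cohort's own "projected reality").
#'
#' @param risk_vectors Named list of predicted-risk vectors on one cohort.
#' @param reference_risks Optional vector of reference-model projected
#'   probabilities (e.g. from [fit_weibull_covariates()] +
#'   [project_probability()]).
#' @param thresholds Risk cutoffs (default 0.10 to 0.30 by 0.05).
#' @return Data frame of class `threshold_report`: one row per model, one
#'   column per threshold, values in percent.
#' @export
threshold_classification <- function(risk_vectors, reference_risks = NULL,
                                     thresholds = c(0.10, 0.15, 0.20, 0.25, 0.30)) {
  if (!is.null(reference_risks))
    risk_vectors <- c(risk_vectors, list(`full Weibull model` = reference_risks))
  rows <- lapply(risk_vectors, function(r)
    vapply(thresholds, function(th) 100 * mean(r >= th), numeric(1)))
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- paste0(">=", format(100 * thresholds, trim = TRUE), "%")
  out <- cbind(model = names(risk_vectors), out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  stopifnot(all(apply(out[, -1, drop = FALSE], 1, function(z) all(diff(z) <= 1e-9))))
  structure(out, class = c("threshold_report", "data.frame"))
}

#' Worst-case unknown-cause sensitivity recoding
#'
#' Returns a copy of the cohort in which every death of unknown cause is
#' recoded as a CV death (the most extreme assumption); the caller reruns
#' the pipeline on the result. Never decreases the CV event count.
#'
#' @param cohort A `cohort`.
#' @return The recoded `cohort`.
#' @export
worst_case_sensitivity <- function(cohort) {
  df <- as.data.frame(cohort)
  df$death_cause[df$status == "dead" & df$death_cause == "unknown"] <- "cv"
  new_cohort(df, attr(cohort, "provenance"))
}

age_band <- function(age, breaks = c(70, 75, 80, 85, 90, Inf)) {
  upper <- c(breaks[-c(1, length(breaks))] - 1, "")
  cut(age, breaks = breaks, right = FALSE,
      labels = paste0(utils::head(breaks, -1), "-", upper))
}

#' Age-sex strata targets matching a cohort's own structure
#'
#' Convenience constructor: counts the cohort's 5-year age band x sex cells
#' (bands 70-74 ... 90+ by default). For a pseudopopulation representative
#' of an external population, supply the external counts instead.
#'
#' @param cohort A `cohort`.
#' @param breaks Age band breakpoints.
#' @return Data frame with `age_band`, `sex`, `count`.
#' @export
make_strata_targets <- function(cohort, breaks = c(70, 75, 80, 85, 90, Inf)) {
  tab <- as.data.frame(table(age_band = age_band(cohort$age, breaks),
                             sex = cohort$sex), stringsAsFactors = FALSE)
  names(tab)[3] <- "count"
  tab[tab$count > 0, , drop = FALSE]
}

#' Stratified resampling to an external age-sex structure
#'
#' Builds pseudopopulation replicates by sampling cohort records with
#' replacement within each age-band x sex stratum up to the target count, so
#' each replicate matches the target population exactly in size and
#' demographic structure.
#'
#' @param cohort A `cohort`.
#' @param targets Data frame with `age_band`, `sex`, `count` (see
#'   [make_strata_targets()]).
#' @param n_replicates Number of replicates (default 5).
#' @param seed Integer seed; replicate seeds are derived as `seed + index`.
#' @param breaks Age band breakpoints used to assign cohort records.
#' @return List of `cohort` replicates.
#' @export
pseudopopulation_resample <- function(cohort, targets, n_replicates = 5,
                                      seed = 1,
                                      breaks = c(70, 75, 80, 85, 90, Inf)) {
  df <- as.data.frame(cohort)
  band <- as.character(age_band(df$age, breaks))
  lapply(seq_len(n_replicates), function(rep_i) {
    set.seed(seed + rep_i)
    idx <- unlist(lapply(seq_len(nrow(targets)), function(k) {
      pool <- which(band == targets$age_band[k] & df$sex == targets$sex[k])
      if (!length(pool))
        stop(sprintf("no source records in stratum %s / %s",
                     targets$age_band[k], targets$sex[k]))
      sample(pool, targets$count[k], replace = TRUE)
    }))
    out <- df[idx, , drop = FALSE]
    out$id <- sprintf("%s_r%d_%05d", out$id, rep_i, seq_along(idx))
    new_cohort(out)
  })
}

#' Risk predictions for hypothetical profiles across the age span
#'
#' Evaluates every equation of a registry over an age sweep for stylised
#' high-, medium- and low-risk profiles of each sex: the high-risk profile
#' is a diabetic current smoker with SBP 180 mmHg, total cholesterol
#' 8 mmol/l and HDL 1 mmol/l; the low-risk profile a non-diabetic non-smoker
#' with SBP 120, total cholesterol 4 and HDL 2; the medium profile uses the
#' emulated cohort's mean values.
#'
#' @param registry Named list of `risk_equation`s.
#' @param ages Ages to sweep (default 60 to 100).
#' @return Long data frame: `equation`, `profile`, `sex`, `age`, `risk`.
#' @export
profile_sweep <- function(registry = default_equation_registry(),
                          ages = 60:100) {
  profiles <- list(
    high = list(sbp = 180, total_chol = 8, hdl_chol = 1,
                smoker = TRUE, diabetes = TRUE),
    medium = list(sbp = 147.0, total_chol = 5.6, hdl_chol = 1.5,
                  smoker = FALSE, diabetes = FALSE),
    low = list(sbp = 120, total_chol = 4, hdl_chol = 2,
               smoker = FALSE, diabetes = FALSE))
  grid <- expand.grid(equation = names(registry), profile = names(profiles),
                      sex = c("male", "female"), stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(grid)), function(k) {
    pr <- c(profiles[[grid$profile[k]]],
            list(age = ages, sex = rep(grid$sex[k], length(ages))))
    data.frame(equation = grid$equation[k], profile = grid$profile[k],
               sex = grid$sex[k], age = ages,
               risk = suppressWarnings(
                 predict_risk(registry[[grid$equation[k]]], pr)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
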