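#' Kaplan-Meier fit with Greenwood variance
#'
#' Product-limit estimator of the survival function with non-cardiovascular
#' deaths encoded upstream as censorings (the validation deliberately does
#' not model competing events). Thin wrapper around [survival::survfit()]
#' exposing the step function and the Greenwood variance of `S(t)`.
#'
#' @param times Non-negative follow-up times (years).
#' @param events Logical event indicators (fatal CV event).
#' @return Object of class `km_fit` with `time`, `surv`, `greenwood_var`,
#'   `n_risk`, `n_event` at each distinct event/censoring time, and
#'   `max_time`, the largest observed time.
#' @export
kaplan_meier <- function(times, events) {
  stopifnot(length(times) == length(events))
  if (any(times < 0)) stop("negative follow-up time")
  events <- as.logical(events)
  if (!any(events)) warning("no events: survival is identically 1")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1, conf.type = "plain")
  structure(list(time = fit$time, surv = fit$surv,
                 # survfit std.err is the SE of the cumulative hazard (log S)
                 greenwood_var = fit$surv^2 * fit$std.err^2,
                 n_risk = fit$n.risk, n_event = fit$n.event,
                 n = length(times), max_time = max(times)),
            class = "km_fit")
}

#' Evaluate a Kaplan-Meier step function
#'
#' Right-continuous convention: `S(t)` at an event time includes that event.
#'
#' @param fit A `km_fit`.
#' @param t Evaluation times (vectorised); must not exceed the largest
#'   observed time.
#' @return Survival probabilities.
#' @export
km_survival <- function(fit, t) {
  if (any(t > fit$max_time))
    stop("horizon beyond the last observed time; Kaplan-Meier does not ",
         "extrapolate - use a Weibull projection instead")
  idx <- findInterval(t, fit$time)
  ifelse(idx == 0, 1, fit$surv[pmax(idx, 1)])
}

#' Greenwood variance of S(t) at given times
#' @param fit A `km_fit`.
#' @param t Evaluation times.
#' @return Variances of the survival estimate (0 before the first event).
#' @export
km_variance <- function(fit, t) {
  idx <- findInterval(t, fit$time)
  v <- ifelse(idx == 0, 0, fit$greenwood_var[pmax(idx, 1)])
  v[is.na(v)] <- 0
  v
}

#' "Actual" event probability from a Kaplan-Meier fit
#'
#' @param fit A `km_fit`.
#' @param horizon Horizon in years, within the observed follow-up range.
#' @return `1 - S(horizon)`.
#' @export
actual_probability_km <- function(fit, horizon) {
  1 - km_survival(fit, horizon)
}

#' Weibull regression with a categorical risk-group covariate
#'
#' Maximum-likelihood Weibull survival regression with right censoring
#' (via [survival::survreg()]): a common shape across groups and
#' group-specific scales through categorical contrasts. Used to project
#' "actual" event probabilities beyond the observed follow-up. A group with
#' zero events is kept (its likelihood contribution is censoring-only) with a
#' warning.
#'
#' @param times,events Follow-up years and logical CV-event indicators.
#' @param group Group labels (decile groups in the validation pipeline).
#' @param shared_shape If `FALSE`, fits a separate shape per group.
#' @return Object of class `weibull_group_fit` with `shape` (per group if not
#'   shared), per-group `scale` (years), `group_labels` and `loglik`.
#' @export
fit_weibull_groups <- function(times, events, group, shared_shape = TRUE) {
  stopifnot(length(times) == length(events), length(times) == length(group))
  events <- as.logical(events)
  group <- factor(group)
  zero_ev <- tapply(events, group, sum) == 0
  if (any(zero_ev))
    warning("group(s) without events: ",
            paste(levels(group)[zero_ev], collapse = ", "),
            "; projected probabilities may be near 0")
  t_fit <- pmax(times, 1e-8)       # survreg requires strictly positive times
  if (shared_shape) {
    fit <- if (nlevels(group) > 1) {
      survival::survreg(survival::Surv(t_fit, events) ~ group, dist = "weibull")
    } else {
      survival::survreg(survival::Surv(t_fit, events) ~ 1, dist = "weibull")
    }
    lp <- c(fit$coefficients[1] +
              c(0, fit$coefficients[-1][seq_len(nlevels(group) - 1)]))
    out <- list(shape = 1 / fit$scale, scale = exp(lp),
                group_labels = levels(group), loglik = fit$loglik[2],
                shared_shape = TRUE)
  } else {
    subfits <- lapply(levels(group), function(g) {
      i <- group == g
      survival::survreg(survival::Surv(t_fit[i], events[i]) ~ 1, dist = "weibull")
    })
    out <- list(shape = vapply(subfits, function(f) 1 / f$scale, numeric(1)),
                scale = vapply(subfits, function(f) exp(f$coefficients[1]), numeric(1)),
                group_labels = levels(group),
                loglik = sum(vapply(subfits, function(f) f$loglik[2], numeric(1))),
                shared_shape = FALSE)
  }
  names(out$scale) <- levels(group)
  if (!out$shared_shape) names(out$shape) <- levels(group)
  structure(out, class = "weibull_group_fit")
}

#' Full-covariate Weibull survival model
#'
#' The reference model of the threshold analysis: Weibull regression of the
#' fatal CV outcome on sex, systolic blood pressure, total and HDL
#' cholesterol, smoking, diabetes and age, fitted on the cohort itself.
#'
#' @param cohort A `cohort`.
#' @param events Logical CV-event indicators aligned with the cohort (by
#'   default, dead with cause `"cv"`).
#' @return Object of class `weibull_covariate_fit`.
#' @export
fit_weibull_covariates <- function(cohort, events = cv_events(cohort)) {
  df <- as.data.frame(cohort)
  df$male <- as.numeric(df$sex == "male")
  t_fit <- pmax(df$followup_years, 1e-8)
  fit <- survival::survreg(
    survival::Surv(t_fit, events) ~ male + sbp + total_chol + hdl_chol +
      smoker + diabetes + age,
    data = df, dist = "weibull")
  structure(list(shape = 1 / fit$scale, coefficients = fit$coefficients,
                 loglik = fit$loglik[2], fit = fit),
            class = "weibull_covariate_fit")
}

#' Fatal-CV event indicator of a cohort
#'
#' Deaths of unknown cause count as non-CV (the primary-analysis convention);
#' use [worst_case_sensitivity()] for the opposite extreme.
#'
#' @param cohort A `cohort`.
#' @return Logical vector.
#' @export
cv_events <- function(cohort) {
  cohort$status == "dead" & cohort$death_cause == "cv"
}

#' Projected event probability from a fitted Weibull model
#'
#' `1 - S(horizon)` under the fitted model; projection beyond the observed
#' follow-up is the purpose of the Weibull fit.
#'
#' @param fit A `weibull_group_fit` or `weibull_covariate_fit`.
#' @param horizon Horizon in years.
#' @param group For group fits: label(s) of the group(s) to project
#'   (default: all groups).
#' @param profile For covariate fits: a data frame of covariates (a cohort
#'   works) giving one projection per row.
#' @return Event probabilities.
#' @export
project_probability <- function(fit, horizon, group = NULL, profile = NULL) {
  if (inherits(fit, "weibull_group_fit")) {
    if (is.null(group)) group <- fit$group_labels
    g <- as.character(group)
    shape <- if (fit$shared_shape) fit$shape else fit$shape[g]
    1 - exp(-(horizon / fit$scale[g])^shape)
  } else if (inherits(fit, "weibull_covariate_fit")) {
    if (is.null(profile)) stop("covariate fit needs a 'profile' data frame")
    df <- as.data.frame(profile)
    df$male <- as.numeric(df$sex == "male")
    lp <- stats::predict(fit$fit, newdata = df, type = "lp")
    1 - exp(-(horizon * exp(-lp))^fit$shape)
  } else stop("unsupported fit object")
}

#' Weibull diagnostic series per group
#'
#' For each group, transforms the Kaplan-Meier estimate to
#' `log(-log S(t))` versus `log t` at event times; under a Weibull model the
#' series is linear (slope = shape) and parallel across groups when the shape
#' is common. Groups with fewer than two usable event times are skipped with
#' a warning.
#'
#' @param times,events,group As in [fit_weibull_groups()].
#' @return Data frame with `group`, `log_time`, `cloglog_surv`, plus an
#'   attribute `r_squared`: per-group R-squared of the straight-line fit.
#' @export
weibull_diagnostics <- function(times, events, group) {
  group <- factor(group)
  out <- list(); r2 <- c()
  for (g in levels(group)) {
    i <- group == g
    fit <- suppressWarnings(kaplan_meier(times[i], events[i]))
    keep <- fit$n_event > 0 & fit$surv > 0 & fit$surv < 1
    if (sum(keep) < 2) {
      warning("group '", g, "' has fewer than 2 usable event times; skipped")
      next
    }
    x <- log(fit$time[keep]); y <- log(-log(fit$surv[keep]))
    out[[g]] <- data.frame(group = g, log_time = x, cloglog_surv = y,
                           stringsAsFactors = FALSE)
    r2[g] <- summary(stats::lm(y ~ x))$r.squared
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  attr(res, "r_squared") <- r2
  res
}

#' Event rate per 1,000 person-years with Poisson exact confidence interval
#'
#' Garwood chi-square inversion of the Poisson count.
#'
#' @param n_events Number of events (>= 0).
#' @param person_years Person-years at risk (> 0).
#' @param conf Confidence level (default 0.95).
#' @return List with `rate`, `ci_lower`, `ci_upper` (per 1,000 person-years),
#'   `n_events` and `person_years`.
#' @export
event_rate <- function(n_events, person_years, conf = 0.95) {
  if (person_years <= 0) stop("person_years must be positive")
  if (n_events < 0) stop("n_events must be non-negative")
  a <- (1 - conf) / 2
  lower <- if (n_events == 0) 0 else stats::qchisq(a, 2 * n_events) / 2
  upper <- stats::qchisq(1 - a, 2 * n_events + 2) / 2
  list(rate = 1000 * n_events / person_years,
       ci_lower = 1000 * lower / person_years,
       ci_upper = 1000 * upper / person_years,
       n_events = n_events, person_years = person_years)
}
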