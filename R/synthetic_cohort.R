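#' Baseline specification of a BIS-like cohort of older persons
#'
#' Defaults emulate the marginal baseline distributions of a population-based
#' Berlin cohort of persons aged 70+: n = 1,657 with 734 men / 923 women,
#' sex-specific means for age (80.2 / 79.2, SD 6.7 / 6.6 years), systolic
#' blood pressure (147.3 / 146.7, SD 22.8 / 22.7 mmHg), total cholesterol
#' (5.1 / 5.9, SD 1.1 / 1.2 mmol/l), HDL cholesterol (1.3 / 1.7, SD 0.4
#' mmol/l), and prevalences of current smoking (6.4% / 4.2%), diabetes
#' (27.2% / 23.2%) and antihypertensive treatment (75.3% / 76.3%).
#' Covariates are independent truncated normals / Bernoullis (the emulated
#' study reports only marginals).
#'
#' @param n Cohort size.
#' @param male_fraction Proportion male.
#' @param prior_mi_prev Prevalence of self-reported prior myocardial
#'   infarction (0 by default: the emulated analysis set has them excluded;
#'   raise it to exercise the inclusion flow).
#' @param ... Overrides of any element of the returned spec.
#' @return List of class `cohort_spec`; continuous entries are
#'   `c(male mean, female mean, male sd, female sd, min, max)`.
#' @export
bis_cohort_spec <- function(n = 1657, male_fraction = 734 / 1657,
                            prior_mi_prev = 0, ...) {
  spec <- list(
    n = n, male_fraction = male_fraction,
    age = list(mean = c(male = 80.2, female = 79.2),
               sd = c(male = 6.7, female = 6.6), min = 70, max = 105),
    sbp = list(mean = c(male = 147.3, female = 146.7),
               sd = c(male = 22.8, female = 22.7), min = 80, max = 240),
    total_chol = list(mean = c(male = 5.1, female = 5.9),
                      sd = c(male = 1.1, female = 1.2), min = 2, max = 12),
    hdl_chol = list(mean = c(male = 1.3, female = 1.7),
                    sd = c(male = 0.4, female = 0.4), min = 0.5, max = 3.5),
    smoker_prev = c(male = 0.064, female = 0.042),
    diabetes_prev = c(male = 0.272, female = 0.232),
    antihtn_prev = c(male = 0.753, female = 0.763),
    prior_mi_prev = prior_mi_prev)
  dots <- list(...)
  bad <- setdiff(names(dots), names(spec))
  if (length(bad)) stop("unknown spec element(s): ", paste(bad, collapse = ", "))
  spec[names(dots)] <- dots
  for (v in c("age", "sbp", "total_chol", "hdl_chol"))
    if (spec[[v]]$min > min(spec[[v]]$mean) || max(spec[[v]]$mean) > spec[[v]]$max)
      stop("infeasible truncation bounds for '", v, "'")
  structure(spec, class = "cohort_spec")
}

rtruncnorm <- function(n, mean, sd, lo, hi) {
  # inverse-CDF sampling of a truncated normal
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Generate the baseline table of a synthetic cohort
#'
#' @param spec A `cohort_spec`.
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @return A `cohort` with follow-up fields set to zero-length follow-up
#'   (`followup_years = NA`) awaiting [simulate_followup()].
#' @export
generate_baseline <- function(spec = bis_cohort_spec(), seed = 1) {
  set.seed(seed)
  n <- spec$n
  n_male <- round(n * spec$male_fraction)
  sex <- c(rep("male", n_male), rep("female", n - n_male))
  draw <- function(par, integer = FALSE) {
    x <- rtruncnorm(n, par$mean[sex], par$sd[sex], par$min, par$max)
    if (integer) round(x) else x
  }
  df <- data.frame(
    id = sprintf("P%04d", seq_len(n)),
    age = draw(spec$age, integer = TRUE),
    sex = sex,
    sbp = draw(spec$sbp),
    total_chol = draw(spec$total_chol),
    hdl_chol = draw(spec$hdl_chol),
    stringsAsFactors = FALSE)
  # keep HDL strictly below total cholesterol
  df$hdl_chol <- pmin(df$hdl_chol, df$total_chol - 0.3)
  df$smoker <- stats::runif(n) < spec$smoker_prev[sex]
  df$diabetes <- stats::runif(n) < spec$diabetes_prev[sex]
  df$antihypertensive <- stats::runif(n) < spec$antihtn_prev[sex]
  pm_prev <- if (length(spec$prior_mi_prev) == 1) rep(spec$prior_mi_prev, 2)
             else spec$prior_mi_prev
  names(pm_prev) <- c("male", "female")
  df$prior_mi <- ifelse(stats::runif(n) < pm_prev[sex], "yes", "no")
  df$followup_years <- NA_real_
  df$status <- NA_character_
  df$death_cause <- "not_applicable"
  new_cohort(df)
}

#' Ground-truth event model of the synthetic scenario
#'
#' Two cause-specific proportional-hazards Weibull models (fatal CV events;
#' competing non-CV death) over the follow-up time scale, exponential loss to
#' follow-up, fixed administrative censoring, and independent masking of the
#' recorded cause of death. Baseline scales were calibrated once so the
#' default scenario reproduces the emulated study's rate environment
#' (about 16 recorded CV deaths and 44 deaths overall per 1,000
#' person-years, median follow-up around 5 years); they are frozen here,
#' not re-tuned per run.
#'
#' @param cv_scale,cv_shape Baseline Weibull scale (years) and shape of the
#'   CV-death model at the centered covariate profile.
#' @param cv_betas Named log-hazard coefficients of the CV model.
#' @param noncv_scale,noncv_shape,noncv_betas Same for the competing
#'   non-CV-death model.
#' @param centering Named centering constants shared by both models.
#' @param admin_censor_years Fixed administrative censoring horizon (years).
#' @param lost_rate Exponential loss-to-follow-up hazard (per year).
#' @param unknown_cause_fraction Proportion of deaths whose recorded cause is
#'   masked to "unknown", independent of the true cause.
#' @return List of class `true_event_model`.
#' @export
bis_event_model <- function(
    cv_scale = 36.3, cv_shape = 1.4,
    cv_betas = c(age = 0.08, male = 0.35, sbp = 0.010, total_chol = 0.10,
                 hdl_chol = -0.35, smoker = 0.55, diabetes = 0.55),
    noncv_scale = 25.8, noncv_shape = 1.5,
    noncv_betas = c(age = 0.095, male = 0.40, sbp = 0.002, total_chol = -0.05,
                    hdl_chol = -0.15, smoker = 0.70, diabetes = 0.45),
    centering = c(age = 79.7, male = 0.443, sbp = 147.0, total_chol = 5.6,
                  hdl_chol = 1.5, smoker = 0, diabetes = 0),
    admin_censor_years = 5.2, lost_rate = 0.005,
    unknown_cause_fraction = 44 / 324) {
  stopifnot(cv_shape > 0, noncv_shape > 0,
            unknown_cause_fraction >= 0, unknown_cause_fraction <= 1)
  structure(list(
    cv = list(scale = cv_scale, shape = cv_shape, betas = cv_betas),
    noncv = list(scale = noncv_scale, shape = noncv_shape, betas = noncv_betas),
    centering = centering,
    admin_censor_years = admin_censor_years, lost_rate = lost_rate,
    unknown_cause_fraction = unknown_cause_fraction),
    class = "true_event_model")
}

model_lp <- function(sub, centering, cohort) {
  df <- as.data.frame(cohort)
  df$male <- as.numeric(df$sex == "male")
  lp <- 0
  for (k in names(sub$betas))
    lp <- lp + sub$betas[[k]] * (df[[k]] - centering[[k]])
  lp
}

# per-person Weibull scale under proportional hazards:
# h(t) = h0(t) exp(lp)  <=>  scale_i = scale0 * exp(-lp / shape)
model_scales <- function(sub, centering, cohort) {
  sub$scale * exp(-model_lp(sub, centering, cohort) / sub$shape)
}

#' Simulate follow-up outcomes for a baseline cohort
#'
#' Draws latent CV and non-CV death times from the ground-truth Weibull
#' models given each participant's covariates, plus an exponential
#' loss-to-follow-up time; the observed follow-up is the earliest of these
#' and the administrative censoring horizon. A fraction of deaths has the
#' recorded cause masked to `"unknown"`, independent of the true cause,
#' which is retained in hidden audit columns (`.true_cause`, `.t_cv`) for
#' testing only and never serialized unless `debug = TRUE` in
#' [write_cohort()].
#'
#' @param cohort A baseline `cohort` from [generate_baseline()].
#' @param model A `true_event_model`.
#' @param seed Integer seed.
#' @return The `cohort` with `followup_years`, `status` and `death_cause`
#'   filled in.
#' @export
simulate_followup <- function(cohort, model = bis_event_model(), seed = 1) {
  set.seed(seed)
  n <- nrow(cohort)
  draw_t <- function(sub) {
    sc <- model_scales(sub, model$centering, cohort)
    if (sub$scale == Inf) rep(Inf, n) else stats::rweibull(n, sub$shape, sc)
  }
  t_cv <- draw_t(model$cv)
  t_ncv <- draw_t(model$noncv)
  t_loss <- if (model$lost_rate > 0) stats::rexp(n, model$lost_rate) else rep(Inf, n)
  t_adm <- rep(model$admin_censor_years, n)
  t_obs <- pmin(t_cv, t_ncv, t_loss, t_adm)
  cause <- rep("not_applicable", n)
  cause[t_obs == t_cv] <- "cv"
  cause[t_obs == t_ncv] <- "non_cv"
  dead <- cause != "not_applicable"
  masked <- dead & stats::runif(n) < model$unknown_cause_fraction
  df <- as.data.frame(cohort)
  df$followup_years <- t_obs
  df$status <- ifelse(dead, "dead", "alive_censored")
  df$death_cause <- ifelse(masked, "unknown", cause)
  df$.true_cause <- cause
  df$.t_cv <- t_cv
  new_cohort(df, attr(cohort, "provenance"))
}

#' Ground-truth CV event probability, ignoring competing events
#'
#' Closed-form net risk under the generator's CV model:
#' `1 - exp(-(horizon / scale_i)^shape)`. This is the analytic oracle used in
#' parameter-recovery and end-to-end self-consistency checks: a perfectly
#' calibrated "risk score" for data produced by [simulate_followup()].
#'
#' @param model A `true_event_model`.
#' @param profile A `cohort` or data frame of covariates.
#' @param horizon Horizon in years.
#' @return Event probabilities, one per row of `profile`.
#' @export
true_probability <- function(model, profile, horizon) {
  sc <- model_scales(model$cv, model$centering, profile)
  1 - exp(-(horizon / sc)^model$cv$shape)
}

#' Generate a complete synthetic cohort in one call
#'
#' @param spec A `cohort_spec`.
#' @param model A `true_event_model`.
#' @param seed Integer seed (baseline and follow-up draws are derived from
#'   it deterministically).
#' @return A `cohort` with baseline and follow-up fields.
#' @export
generate_cohort <- function(spec = bis_cohort_spec(),
                            model = bis_event_model(), seed = 1) {
  base <- generate_baseline(spec, seed = seed)
  simulate_followup(base, model, seed = seed + 1L)
}
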