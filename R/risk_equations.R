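#' @useDynLib riskvalid, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Weibull baseline survival of a cause-specific risk model
#'
#' The SCORE family models each cause of death (coronary heart disease;
#' non-coronary cardiovascular disease) with a Weibull baseline on the age
#' scale: `S0(age) = exp(-exp(alpha) * (age - age_origin)^p)`.
#'
#' @param age Attained age in years (vectorised); must exceed `age_origin`.
#' @param model A `weibull_cause_model` (see [weibull_cause_model()]).
#' @return Survival probabilities in (0, 1].
#' @export
baseline_survival_weibull <- function(age, model) {
  if (any(age <= model$age_origin))
    stop(sprintf("age must exceed the model's age origin (%g years)",
                 model$age_origin))
  exp(-exp(model$alpha) * (age - model$age_origin)^model$p)
}

#' Construct a cause-specific Weibull risk model
#'
#' @param alpha Log-scale baseline parameter.
#' @param p Shape exponent (> 0).
#' @param betas Named numeric vector of log-hazard coefficients.
#' @param centering Named numeric vector of centering constants (one per beta;
#'   0 allowed).
#' @param age_origin Age subtracted inside the baseline (20 for SCORE).
#' @return An object of class `weibull_cause_model`.
#' @export
weibull_cause_model <- function(alpha, p, betas, centering, age_origin = 20) {
  stopifnot(is.numeric(alpha), length(alpha) == 1, p > 0)
  betas <- unlist(betas); centering <- unlist(centering)
  missing_c <- setdiff(names(betas), names(centering))
  if (length(missing_c))
    stop("no centering constant for beta(s): ", paste(missing_c, collapse = ", "))
  structure(list(alpha = alpha, p = p, betas = betas,
                 centering = centering[names(betas)], age_origin = age_origin),
            class = "weibull_cause_model")
}

linear_predictor <- function(profile, betas, centering) {
  lp <- 0
  for (k in names(betas)) {
    x <- profile[[k]]
    if (is.null(x)) stop("profile is missing risk factor '", k, "'")
    lp <- lp + betas[[k]] * (as.numeric(x) - centering[[k]])
  }
  lp
}

#' Cause-specific risk over a horizon (SCORE two-cause Weibull family)
#'
#' Conditional on survival to the attained age, the risk of dying of the
#' modelled cause within `horizon` years is `1 - S(age + horizon) / S(age)`
#' where `S(age) = S0(age)^exp(w)` and `w` is the centred linear predictor.
#'
#' @param profile A list/data frame of risk factors (vectorised columns are
#'   supported); must contain every factor named in `model$betas` plus `age`.
#' @param model A `weibull_cause_model`.
#' @param horizon Horizon in years.
#' @return Risks in \[0, 1).
#' @export
cause_specific_risk <- function(profile, model, horizon) {
  w <- linear_predictor(profile, model$betas, model$centering)
  s_now <- baseline_survival_weibull(profile$age, model)^exp(w)
  s_then <- baseline_survival_weibull(profile$age + horizon, model)^exp(w)
  1 - s_then / s_now
}

#' Combine two cause-specific risks into an overall fatal CV risk
#'
#' The original SCORE publication summed the coronary and non-coronary risks,
#' which can exceed one for high-risk profiles. The corrected combination
#' assumes cause-specific independence:
#' `R = 1 - (1 - R_chd) * (1 - R_non_chd)`, which always stays in \[0, 1\].
#'
#' @param r_chd,r_non_chd Cause-specific risks in \[0, 1\] (vectorised).
#' @param rule `"corrected_product"` (default) or `"additive_original"`. The
#'   additive rule may exceed 1; any such value triggers a warning and is
#'   returned un-clipped.
#' @return Overall risks.
#' @export
combine_cause_risks <- function(r_chd, r_non_chd,
                                rule = c("corrected_product", "additive_original")) {
  rule <- match.arg(rule)
  if (any(r_chd < 0 | r_chd > 1 | r_non_chd < 0 | r_non_chd > 1))
    stop("cause-specific risks must lie in [0, 1]")
  if (rule == "corrected_product") {
    1 - (1 - r_chd) * (1 - r_non_chd)
  } else {
    out <- r_chd + r_non_chd
    if (any(out > 1))
      warning(sprintf("%d additive risk(s) exceed 1 (implausible probability); not clipped",
                      sum(out > 1)))
    out
  }
}

#' Construct a linear-predictor-on-baseline-survival model (SCORE OP family)
#'
#' @param baseline_survival Named numeric vector: horizon (years, as name) ->
#'   baseline survival `S0(t)` in (0, 1].
#' @param betas,centering Named numeric vectors as in [weibull_cause_model()].
#' @return An object of class `lp_survival_model`.
#' @export
lp_survival_model <- function(baseline_survival, betas, centering) {
  baseline_survival <- unlist(baseline_survival)
  if (any(baseline_survival <= 0 | baseline_survival > 1))
    stop("baseline survival values must lie in (0, 1]")
  betas <- unlist(betas); centering <- unlist(centering)
  missing_c <- setdiff(names(betas), names(centering))
  if (length(missing_c))
    stop("no centering constant for beta(s): ", paste(missing_c, collapse = ", "))
  structure(list(baseline_survival = baseline_survival, betas = betas,
                 centering = centering[names(betas)]),
            class = "lp_survival_model")
}

#' Risk under a linear-predictor-on-baseline-survival model
#'
#' `risk = 1 - S0(horizon)^exp(lp)` with `lp` the centred linear predictor.
#'
#' @param profile Risk-factor list/data frame (vectorised).
#' @param model An `lp_survival_model`.
#' @param horizon Horizon in years; must be declared in the model's
#'   `baseline_survival`.
#' @return Risks in \[0, 1).
#' @export
score_op_risk <- function(profile, model, horizon) {
  s0 <- model$baseline_survival[as.character(horizon)]
  if (is.na(s0))
    stop(sprintf("horizon %g years is not declared in the model's baseline survival",
                 horizon))
  lp <- linear_predictor(profile, model$betas, model$centering)
  1 - unname(s0)^exp(lp)
}

EQUATION_NAMES <- c("SCORE-H", "SCORE-L", "SCORE OP-H", "SCORE OP-L",
                    "SCORE OP-H 5y", "SCORE OP-L 5y")

#' Construct a validated risk equation
#'
#' @param name Equation name (one of the six validated equations, or any
#'   user-defined name).
#' @param family `"score_weibull_two_cause"` or `"score_op_linear_predictor"`.
#' @param horizon Horizon in years (5 or 10).
#' @param sexes Named list with elements `male` and `female`. For the
#'   two-cause family each element is `list(chd = <weibull_cause_model>,
#'   non_chd_cvd = <weibull_cause_model>)`; for the linear-predictor family
#'   each is an `lp_survival_model`.
#' @param combination_rule Combination rule for the two-cause family.
#' @param provenance Free-text citation of the source publication/table;
#'   required.
#' @param region Optional risk-region tag (`"high"`/`"low"`).
#' @return An object of class `risk_equation`.
#' @export
risk_equation <- function(name, family = c("score_weibull_two_cause",
                                           "score_op_linear_predictor"),
                          horizon, sexes, combination_rule = "corrected_product",
                          provenance, region = NA_character_) {
  family <- match.arg(family)
  if (missing(provenance) || is.null(provenance) || !nzchar(provenance))
    stop("equation '", name, "': provenance string is required")
  for (s in c("male", "female")) {
    sub <- sexes[[s]]
    if (is.null(sub))
      stop("equation '", name, "': missing submodel for sex '", s, "'")
    if (family == "score_weibull_two_cause") {
      if (!inherits(sub$chd, "weibull_cause_model") ||
          !inherits(sub$non_chd_cvd, "weibull_cause_model"))
        stop("equation '", name, "': sex '", s,
             "' needs weibull_cause_model fields 'chd' and 'non_chd_cvd'")
    } else if (!inherits(sub, "lp_survival_model")) {
      stop("equation '", name, "': sex '", s, "' must be an lp_survival_model")
    }
    if (family == "score_op_linear_predictor" &&
        !as.character(horizon) %in% names(sub$baseline_survival))
      stop("equation '", name, "': baseline survival does not declare horizon ",
           horizon)
  }
  structure(list(name = name, family = family, horizon = horizon,
                 sexes = sexes, combination_rule = combination_rule,
                 provenance = provenance, region = region),
            class = "risk_equation")
}

#' @export
print.risk_equation <- function(x, ...) {
  cat(sprintf("<risk_equation> %s (%s, %g-year horizon)\n",
              x$name, x$family, x$horizon))
  cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Predicted risk for one profile or a whole cohort
#'
#' Applies the sex-specific submodel, and for the two-cause family combines
#' the coronary and non-coronary risks with the equation's combination rule.
#' Ages beyond the development range of the equations (65 for SCORE, 80 for
#' SCORE OP) are extrapolated at face value with a one-time warning.
#'
#' @param equation A `risk_equation`.
#' @param profile List/data frame with `age`, `sex` and the risk factors the
#'   equation uses; columns may be vectors.
#' @return Numeric vector of predicted risks, one per row of `profile`.
#' @export
predict_risk <- function(equation, profile) {
  sex <- as.character(profile$sex)
  if (any(is.na(sex) | !sex %in% c("male", "female")))
    stop("profile sex must be 'male' or 'female'")
  dev_max <- if (equation$family == "score_weibull_two_cause") 65 else 80
  if (any(profile$age > dev_max))
    warning(sprintf("%s: %d profile(s) older than the development range (> %d y); extrapolating at face value",
                    equation$name, sum(profile$age > dev_max), dev_max))
  out <- numeric(length(sex))
  for (s in c("male", "female")) {
    idx <- sex == s
    if (!any(idx)) next
    sub_prof <- lapply(profile, function(col)
      if (length(col) == length(sex)) col[idx] else col)
    sub <- equation$sexes[[s]]
    out[idx] <- if (equation$family == "score_weibull_two_cause") {
      combine_cause_risks(
        cause_specific_risk(sub_prof, sub$chd, equation$horizon),
        cause_specific_risk(sub_prof, sub$non_chd_cvd, equation$horizon),
        rule = equation$combination_rule)
    } else {
      score_op_risk(sub_prof, sub, equation$horizon)
    }
  }
  out
}

#' Predicted risks for every participant of a cohort
#'
#' @param cohort A `cohort` that already passed [apply_inclusion()] for this
#'   equation's required fields.
#' @param equation A `risk_equation`.
#' @return Numeric risk vector aligned with the cohort rows.
#' @export
predict_cohort <- function(cohort, equation) {
  df <- as.data.frame(cohort)
  needed <- c("age", "sex",
              unique(unlist(lapply(
                if (equation$family == "score_weibull_two_cause")
                  lapply(equation$sexes, function(s) c(names(s$chd$betas),
                                                       names(s$non_chd_cvd$betas)))
                else lapply(equation$sexes, function(s) names(s$betas)),
                identity))))
  needed <- intersect(needed, names(df))
  incomplete <- Reduce(`|`, lapply(df[needed], is.na))
  if (any(incomplete))
    stop("missing risk factor(s) for record(s): ",
         paste(utils::head(df$id[incomplete], 5), collapse = ", "),
         " - run apply_inclusion() first")
  predict_risk(equation, df)
}

#' Pairwise Spearman rank correlations between predicted-risk vectors
#'
#' @param risk_vectors Named list of equal-length numeric vectors (length >= 3).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
score_correlations <- function(risk_vectors) {
  lens <- vapply(risk_vectors, length, integer(1))
  if (length(unique(lens)) != 1) stop("risk vectors have differing lengths")
  if (lens[1] < 3) stop("need at least 3 observations")
  stats::cor(do.call(cbind, risk_vectors), method = "spearman")
}

registry_to_equation <- function(block) {
  fam <- block$family
  mk_wcm <- function(m) weibull_cause_model(
    alpha = m$alpha, p = m$p, betas = m$betas,
    centering = m$centering,
    age_origin = if (is.null(m$age_origin)) 20 else m$age_origin)
  sexes <- lapply(block$sexes[c("male", "female")], function(sub) {
    if (is.null(sub)) return(NULL)
    if (fam == "score_weibull_two_cause") {
      list(chd = mk_wcm(sub$chd), non_chd_cvd = mk_wcm(sub$non_chd_cvd))
    } else {
      lp_survival_model(sub$baseline_survival, sub$betas, sub$centering)
    }
  })
  risk_equation(name = block$name, family = fam,
                horizon = block$horizon_years, sexes = sexes,
                combination_rule = if (is.null(block$combination_rule))
                  "corrected_product" else block$combination_rule,
                provenance = block$provenance,
                region = if (is.null(block$region)) NA_character_ else block$region)
}

#' Load risk equations from a JSON coefficient registry
#'
#' The registry is data, not code: a JSON file with an `equations` array whose
#' blocks carry `name`, `family`, `region`, `horizon_years`,
#' `combination_rule`, per-sex coefficient blocks and a mandatory
#' `provenance` string citing the source publication and table. Structure is
#' validated; coefficient values are taken on trust from the transcriber.
#'
#' @param path Path to a registry JSON file.
#' @return Named list of `risk_equation` objects.
#' @export
load_equation_registry <- function(path) {
  reg <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (is.null(reg$equations)) stop("registry has no 'equations' array")
  eqs <- lapply(reg$equations, registry_to_equation)
  names(eqs) <- vapply(eqs, `[[`, character(1), "name")
  if (anyDuplicated(names(eqs)))
    stop("duplicate equation name(s) in registry")
  eqs
}

#' The shipped default equation registry
#'
#' Loads the SCORE coefficient file (transcribed from the 2003 development
#' publication) together with the SCORE OP stand-in file. The SCORE OP
#' coefficients shipped here are synthetic illustrative values of realistic
#' magnitude, *not* the published ones; real validation work against SCORE OP
#' must supply a registry transcribed from the development publication (the
#' provenance strings in the file repeat this).
#'
#' @return Named list of the six `risk_equation` objects.
#' @export
default_equation_registry <- function() {
  c(load_equation_registry(system.file("extdata", "score_conroy2003.json",
                                       package = "riskvalid", mustWork = TRUE)),
    load_equation_registry(system.file("extdata", "score_op_synthetic.json",
                                       package = "riskvalid", mustWork = TRUE)))
}
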