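test_that("Weibull baseline survival matches the closed form", {
  m <- toy_cause_model(alpha = -5, p = 2)
  # direct arithmetic evaluation of exp(-exp(alpha) * (age - 20)^p)
  expect_equal(baseline_survival_weibull(70, m), exp(-exp(-5) * 2500))
  expect_equal(baseline_survival_weibull(21, m), exp(-exp(-5)))
  # vanishing hazard limit
  expect_equal(baseline_survival_weibull(70, toy_cause_model(alpha = -1e6)), 1)
  # strictly decreasing in age
  ages <- seq(30, 90, by = 5)
  expect_true(all(diff(baseline_survival_weibull(ages, m)) < 0))
  expect_error(baseline_survival_weibull(20, m), "age origin")
})

test_that("cause-specific risk reduces correctly and is monotone", {
  m <- toy_cause_model(alpha = -5, p = 2, betas = c(sbp = 0.02),
                       centering = c(sbp = 120))
  prof <- toy_profile(age = 70, sbp = 120)      # w = 0
  expect_equal(cause_specific_risk(prof, m, 10),
               1 - baseline_survival_weibull(80, m) / baseline_survival_weibull(70, m))
  # null model: zero hazard means zero risk
  expect_equal(cause_specific_risk(prof, toy_cause_model(alpha = -1e6), 10), 0)
  # non-decreasing in SBP for positive beta (numeric sweep)
  risks <- vapply(seq(100, 200, by = 5), function(s)
    cause_specific_risk(toy_profile(age = 70, sbp = s), m, 10), numeric(1))
  expect_true(all(diff(risks) > 0))
  # strictly increasing in horizon and age
  expect_true(cause_specific_risk(prof, m, 10) > cause_specific_risk(prof, m, 5))
  expect_true(cause_specific_risk(toy_profile(age = 75, sbp = 120), m, 10) >
                cause_specific_risk(toy_profile(age = 70, sbp = 120), m, 10))
})

test_that("cause combination rules match hand arithmetic", {
  expect_equal(combine_cause_risks(0, 0.3), 0.3)
  expect_equal(combine_cause_risks(0, 0.3, "additive_original"), 0.3)
  expect_equal(combine_cause_risks(0.5, 0.5), 0.75)
  expect_equal(combine_cause_risks(0.5, 0.5, "additive_original"), 1.0)
  expect_equal(combine_cause_risks(0.7, 0.6), 0.88)
  # the additive original can exceed 1 and must be flagged, not clipped
  expect_warning(r <- combine_cause_risks(0.7, 0.6, "additive_original"),
                 "exceed 1")
  expect_equal(r, 1.3)
  expect_error(combine_cause_risks(1.2, 0.1), "\\[0, 1\\]")
})

test_that("linear-predictor risk honours baseline survival and horizons", {
  m <- lp_survival_model(c(`5` = 0.95, `10` = 0.85),
                         betas = c(sbp = 0.01), centering = c(sbp = 140))
  expect_equal(score_op_risk(toy_profile(sbp = 140), m, 10), 1 - 0.85)  # lp = 0
  expect_error(score_op_risk(toy_profile(), m, 7), "horizon")
  m1 <- lp_survival_model(c(`10` = 1), betas = c(sbp = 0.01),
                          centering = c(sbp = 140))
  expect_equal(score_op_risk(toy_profile(sbp = 190), m1, 10), 0)
  # monotone in a positive-beta factor
  risks <- vapply(seq(100, 200, 10), function(s)
    score_op_risk(toy_profile(sbp = s), m, 10), numeric(1))
  expect_true(all(diff(risks) > 0))
})

test_that("the default registry is complete and validated", {
  reg <- default_equation_registry()
  expect_setequal(names(reg), c("SCORE-H", "SCORE-L", "SCORE OP-H",
                                "SCORE OP-L", "SCORE OP-H 5y", "SCORE OP-L 5y"))
  expect_true(all(vapply(reg, function(e) nzchar(e$provenance), logical(1))))
  expect_equal(reg[["SCORE-H"]]$horizon, 10)
  expect_equal(reg[["SCORE OP-L 5y"]]$horizon, 5)
})

test_that("registry validation rejects structural defects", {
  reg <- jsonlite::read_json(system.file("extdata", "score_conroy2003.json",
                                         package = "riskvalid"),
                             simplifyVector = TRUE, simplifyDataFrame = FALSE)
  broken <- reg
  broken$equations[[1]]$sexes$female <- NULL
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(broken, path, auto_unbox = TRUE, digits = NA)
  expect_error(load_equation_registry(path), "female")
  broken2 <- reg
  broken2$equations[[1]]$provenance <- NULL
  jsonlite::write_json(broken2, path, auto_unbox = TRUE, digits = NA)
  expect_error(load_equation_registry(path), "provenance")
})

test_that("prediction is deterministic, order-aligned and sex-specific", {
  reg <- default_equation_registry()
  co <- apply_inclusion(generate_cohort(seed = 5))
  r1 <- suppressWarnings(predict_cohort(co, reg[["SCORE-H"]]))
  r2 <- suppressWarnings(predict_cohort(co, reg[["SCORE-H"]]))
  expect_identical(r1, r2)
  expect_length(r1, nrow(co))
  expect_true(all(r1 >= 0 & r1 <= 1))   # corrected product stays in [0, 1]
  # single record equals single-profile computation
  one <- riskvalid:::new_cohort(as.data.frame(co)[7, , drop = FALSE])
  expect_equal(suppressWarnings(predict_cohort(one, reg[["SCORE-H"]])), r1[7])
  # changing only sex changes the risk under sex-specific submodels
  prof <- toy_profile(age = 78, sex = "male")
  pf <- prof; pf$sex <- "female"
  expect_false(isTRUE(all.equal(
    suppressWarnings(predict_risk(reg[["SCORE-H"]], prof)),
    suppressWarnings(predict_risk(reg[["SCORE-H"]], pf)))))
  # missing risk factors abort with the offending id
  df <- as.data.frame(co); df$total_chol[3] <- NA
  expect_error(predict_cohort(riskvalid:::new_cohort(df), reg[["SCORE-H"]]),
               df$id[3])
})

test_that("ages past the development range extrapolate with a warning", {
  reg <- default_equation_registry()
  expect_warning(predict_risk(reg[["SCORE-H"]], toy_profile(age = 80)),
                 "development range")
})

test_that("Spearman correlations are rank-invariant and near 1 for H/L pairs", {
  x <- c(0.1, 0.4, 0.2, 0.9, 0.6)
  m <- score_correlations(list(a = x, b = x^2, c = rev(x)))
  expect_equal(diag(m), c(a = 1, b = 1, c = 1))
  expect_equal(m["a", "b"], 1)          # strictly monotone transform
  expect_equal(m, t(m))
  expect_error(score_correlations(list(a = 1:4, b = 1:5)), "length")

  co <- apply_inclusion(generate_cohort(seed = 9))
  reg <- default_equation_registry()
  risks <- lapply(reg, function(e) suppressWarnings(predict_cohort(co, e)))
  rho <- score_correlations(risks)
  # regional variants agree in rank almost perfectly; the two-cause family's
  # H/L agreement is slightly diluted when covariates are independent, as in
  # the default generator
  expect_gte(rho["SCORE-H", "SCORE-L"], 0.98)
  expect_gte(rho["SCORE OP-H", "SCORE OP-L"], 0.99)
  expect_gte(rho["SCORE OP-H 5y", "SCORE OP-H"], 0.99)
})
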