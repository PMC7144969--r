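test_that("Kaplan-Meier matches the hand product-limit calculation", {
  t <- c(1, 2, 3); e <- c(TRUE, FALSE, TRUE)
  fit <- kaplan_meier(t, e)
  expect_equal(km_survival(fit, 2.5), 2 / 3)
  expect_equal(km_survival(fit, 3), 0)
  expect_equal(km_survival(fit, 0.5), 1)
  expect_equal(actual_probability_km(fit, 2.5), 1 / 3)
  # against the independent reference on a random censored sample
  set.seed(42)
  tt <- rexp(40); ee <- runif(40) < 0.6
  f2 <- kaplan_meier(tt, ee)
  for (q in quantile(tt, c(0.2, 0.5, 0.8)))
    expect_equal(km_survival(f2, q), km_reference(tt, ee, q))
})

test_that("KM equals the empirical survival function without censoring", {
  set.seed(1)
  t <- rexp(30)
  fit <- kaplan_meier(t, rep(TRUE, 30))
  for (q in quantile(t, c(0.1, 0.5, 0.9)))
    expect_equal(km_survival(fit, q), mean(t > q))
  # doubling every record leaves S(t) unchanged
  fit2 <- kaplan_meier(rep(t, 2), rep(TRUE, 60))
  expect_equal(km_survival(fit2, median(t)), km_survival(fit, median(t)))
})

test_that("KM contract cases: no events, variance, no extrapolation", {
  expect_warning(fit <- kaplan_meier(c(1, 2, 3), c(FALSE, FALSE, FALSE)),
                 "no events")
  expect_equal(km_survival(fit, 3), 1)
  f <- kaplan_meier(c(1, 2, 3), c(TRUE, FALSE, TRUE))
  expect_equal(km_variance(f, 0.5), 0)    # zero before the first event
  expect_gt(km_variance(f, 1.5), 0)
  expect_error(km_survival(f, 4), "Weibull")
  expect_error(actual_probability_km(f, 10), "Weibull")
})

test_that("grouped Weibull fit matches an independent likelihood maximisation", {
  set.seed(7)
  t <- rweibull(20, shape = 1.4, scale = 8)
  fit <- fit_weibull_groups(t, rep(TRUE, 20), rep("g1", 20))
  ref <- weibull_mle_reference(t, rep(TRUE, 20))
  expect_equal(unname(fit$shape), unname(ref["shape"]), tolerance = 1e-3)
  expect_equal(unname(fit$scale), unname(ref["scale"]), tolerance = 1e-3)
})

test_that("grouped Weibull fit recovers simulating parameters", {
  set.seed(21)
  n <- 4000
  t1 <- rweibull(n, 1.3, 20); t2 <- rweibull(n, 1.3, 12)
  admin <- 14                                   # ~40% administrative censoring
  times <- pmin(c(t1, t2), admin)
  events <- c(t1, t2) < admin
  group <- rep(c("lo", "hi"), each = n)
  expect_gt(mean(!events), 0.3)
  fit <- fit_weibull_groups(times, events, group)
  expect_lt(abs(fit$shape - 1.3) / 1.3, 0.10)   # shape within 10%
  p10 <- project_probability(fit, 10, group = c("lo", "hi"))
  truth <- 1 - exp(-(10 / c(20, 12))^1.3)
  expect_lt(max(abs(p10 - truth)), 0.02)        # within 2 percentage points
  # invariant to group label permutation: probabilities attach to groups
  fit_perm <- fit_weibull_groups(times, events,
                                 factor(group, levels = c("hi", "lo")))
  expect_equal(project_probability(fit_perm, 10, group = "hi"),
               project_probability(fit, 10, group = "hi"), tolerance = 1e-6)
  # exponential data recover shape ~ 1
  te <- rexp(2000, 1 / 15); ce <- pmin(te, 12)
  fe <- fit_weibull_groups(ce, te < 12, rep("g", 2000))
  expect_lt(abs(fe$shape - 1), 0.08)
})

test_that("projection has the exponential closed form and agrees with KM", {
  set.seed(5)
  te <- rexp(4000, 1 / 15)
  cens <- pmin(te, 10)
  fit <- fit_weibull_groups(cens, te < 10, rep("g", 4000))
  expect_equal(unname(project_probability(fit, 0, group = "g")), 0)
  # shape ~ 1: matches 1 - exp(-t/scale)
  expect_equal(project_probability(fit, 8, group = "g"),
               1 - exp(-(8 / fit$scale)^fit$shape))
  # agreement with KM at an interior time on well-specified data
  km <- kaplan_meier(cens, te < 10)
  expect_lt(abs(project_probability(fit, 5, group = "g") -
                  actual_probability_km(km, 5)), 0.015)
})

test_that("a group without events is kept with a warning", {
  set.seed(3)
  times <- c(rweibull(50, 1.2, 5), runif(30, 0, 4))
  events <- c(rep(TRUE, 50), rep(FALSE, 30))
  group <- rep(c("a", "b"), c(50, 30))
  expect_warning(fit <- fit_weibull_groups(times, events, group), "without events")
  expect_lt(project_probability(fit, 10, group = "b"),
            project_probability(fit, 10, group = "a"))
})

test_that("Weibull diagnostics separate Weibull from bathtub data", {
  set.seed(11)
  tw <- rweibull(600, 1.4, 10)
  tb <- c(rexp(300, 2), 8 + rweibull(300, 6, 2))  # bathtub mixture
  d <- weibull_diagnostics(c(tw, tb), rep(TRUE, 1200),
                           rep(c("weib", "bath"), each = 600))
  r2 <- attr(d, "r_squared")
  expect_gt(r2["weib"], 0.97)
  expect_lt(r2["bath"], r2["weib"])
  expect_warning(weibull_diagnostics(c(1, 2, 3), c(TRUE, FALSE, FALSE),
                                     rep("one", 3)),
                 "skipped")
})

test_that("event rates reproduce the Poisson exact intervals", {
  r_cv <- event_rate(118, 7370.3)
  expect_equal(round(r_cv$rate, 1), 16.0)
  expect_equal(round(r_cv$ci_lower, 1), 13.3)
  expect_equal(round(r_cv$ci_upper, 1), 19.2)
  # cross-check against the base Poisson exact test
  pt <- poisson.test(118)$conf.int * 1000 / 7370.3
  expect_equal(c(r_cv$ci_lower, r_cv$ci_upper), as.numeric(pt), tolerance = 1e-10)
  r0 <- event_rate(0, 100)
  expect_equal(r0$rate, 0)
  expect_equal(r0$ci_lower, 0)
  expect_gt(r0$ci_upper, 0)
  expect_error(event_rate(5, 0), "positive")
  # CI contains the point estimate; width shrinks with more events
  r1 <- event_rate(10, 1000); r2 <- event_rate(1000, 100000)
  expect_true(r1$ci_lower < r1$rate && r1$rate < r1$ci_upper)
  expect_lt(r2$ci_upper - r2$ci_lower, r1$ci_upper - r1$ci_lower)
})
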