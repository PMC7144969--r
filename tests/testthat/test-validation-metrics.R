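test_that("decile grouping produces near-equal, ordered groups", {
  a <- decile_groups(as.numeric(1:100))
  expect_equal(as.vector(table(a$group)), rep(10, 10))
  expect_equal(a$G, 10)
  # groups are ordered by risk
  expect_true(all(diff(tapply(1:100, a$group, max)) > 0))
  # continuous draws: exactly equal group sizes
  set.seed(2)
  b <- decile_groups(runif(1000))
  expect_equal(as.vector(table(b$group)), rep(100, 10))
  expect_error(decile_groups(runif(5), G = 10), "fewer groups")
  expect_warning(d <- decile_groups(rep(0.2, 50)), "identical")
  expect_equal(d$G, 1L)
})

test_that("Nam-D'Agostino matches direct formula arithmetic", {
  tab <- structure(data.frame(group = 1:2, n = c(100, 100),
                              mean_predicted = c(0.1, 0.2),
                              actual = c(0.15, 0.25),
                              actual_var = c(NA, NA),
                              expected_events = c(10, 20),
                              actual_events = c(15, 25)),
                   class = c("calibration_table", "data.frame"))
  nd <- nam_dagostino(tab)
  expect_equal(nd$chi_square, 100 * 0.0025 / 0.09 + 100 * 0.0025 / 0.16)
  expect_equal(nd$chi_square, 4.3403, tolerance = 1e-4)
  expect_equal(nd$df, 2)
  expect_equal(nd$p_value, pchisq(nd$chi_square, 2, lower.tail = FALSE))
  # perfect calibration: chi-square 0, p = 1
  tab0 <- tab; tab0$actual <- tab0$mean_predicted
  expect_equal(nam_dagostino(tab0)$chi_square, 0)
  expect_equal(nam_dagostino(tab0)$p_value, 1)
  # invariant to group order permutation
  expect_equal(nam_dagostino(tab[2:1, ])$chi_square, nd$chi_square)
  # Greenwood-variance variant
  tabg <- tab; tabg$actual_var <- c(0.001, 0.002)
  ndg <- nam_dagostino(tabg, variance = "greenwood")
  expect_equal(ndg$chi_square, 0.0025 / 0.001 + 0.0025 / 0.002)
})

test_that("concordance matches hand-enumerated cases", {
  # pairs (1,2),(1,3) concordant, (2,3) discordant
  expect_equal(harrell_c(c(2, 4, 6), c(TRUE, TRUE, FALSE), c(0.9, 0.3, 0.5)),
               2 / 3)
  # perfect ranking, no censoring
  expect_equal(harrell_c(c(1, 2, 3, 4), rep(TRUE, 4), c(4, 3, 2, 1) / 4), 1)
  # all risks tied: 0.5 by the half-credit convention
  expect_equal(harrell_c(c(1, 2, 3), rep(TRUE, 3), rep(0.2, 3)), 0.5)
  # no comparable pairs
  expect_error(harrell_c(c(1, 1), c(TRUE, TRUE), c(0.1, 0.2)), "comparable")
  # reversal identity without risk ties
  set.seed(8)
  t <- rexp(30); e <- runif(30) < 0.7; r <- runif(30)
  expect_equal(harrell_c(t, e, r) + harrell_c(t, e, -r), 1)
})

test_that("concordance equals the brute-force reference and survival package", {
  set.seed(123)
  for (k in 1:25) {
    n <- sample(5:50, 1)
    t <- round(rexp(n), sample(c(1, 2), 1))   # induce some ties
    e <- runif(n) < 0.7
    r <- round(runif(n), 2)
    if (!any(e)) e[1] <- TRUE
    expect_equal(harrell_c(t, e, r), harrell_c_reference(t, e, r))
  }
  # independent cross-check: survival::concordance on tie-free data
  set.seed(9)
  t <- rexp(60); e <- runif(60) < 0.6; r <- runif(60)
  cs <- survival::concordance(survival::Surv(t, e) ~ r, reverse = TRUE)
  expect_equal(harrell_c(t, e, r), as.numeric(cs$concordance))
})

test_that("leave-one-out concordance values match explicit recomputation", {
  set.seed(4)
  t <- rexp(25); e <- runif(25) < 0.7; r <- runif(25)
  jk <- harrell_c_jackknife(t, e, r)
  direct <- vapply(1:25, function(i) harrell_c(t[-i], e[-i], r[-i]), numeric(1))
  expect_equal(jk, direct)
})

test_that("BCa bootstrap is reproducible and near-percentile for symmetric data", {
  set.seed(31)
  x <- rnorm(80)
  b1 <- bca_bootstrap(x, mean, B = 500, seed = 9)
  b2 <- bca_bootstrap(x, mean, B = 500, seed = 9)
  expect_identical(b1, b2)
  expect_equal(b1$estimate, mean(x))
  # symmetric statistic: BCa ~ percentile interval
  set.seed(9)
  boots <- vapply(1:500, function(b) mean(x[sample.int(80, replace = TRUE)]),
                  numeric(1))
  perc <- quantile(boots, c(0.025, 0.975), names = FALSE)
  expect_lt(abs(b1$ci_lower - perc[1]), 0.03)
  expect_lt(abs(b1$ci_upper - perc[2]), 0.03)
  expect_error(bca_bootstrap(x, mean, B = 100), "at least 200")
  # a statistic failing on most resamples raises, not silently drops:
  # bootstrap resamples contain duplicates, the original sample does not
  bad <- function(d) if (length(unique(d)) < 75) stop("degenerate") else mean(d)
  expect_error(bca_bootstrap(x, bad, B = 200, seed = 1), "failed")
})

test_that("BCa agrees with the boot package on a skewed statistic", {
  skip_if_not_installed("boot")
  set.seed(77)
  x <- rexp(60)
  ours <- bca_bootstrap(x, mean, B = 2000, seed = 5)
  bt <- boot::boot(x, function(d, i) mean(d[i]), R = 2000)
  ci <- boot::boot.ci(bt, type = "bca")$bca[4:5]
  expect_lt(abs(ours$ci_lower - ci[1]), 0.05)
  expect_lt(abs(ours$ci_upper - ci[2]), 0.05)
})

test_that("calibration table and totals behave under known miscalibration", {
  set.seed(14)
  n <- 4000
  p_true <- runif(n, 0.05, 0.4)
  # uncensored binomial outcomes at horizon 5: event times inside, censored after
  event <- runif(n) < p_true
  times <- ifelse(event, runif(n, 0, 5), 6)
  a <- decile_groups(p_true)
  tab <- calibration_table(a, p_true, times, event, horizon = 5,
                           actual_source = "km")
  expect_equal(sum(tab$n), n)
  expect_true(all(diff(tab$mean_predicted) > 0))
  expect_lt(max(abs(tab$actual - tab$mean_predicted)), 0.07)
  tot <- expected_and_actual_events(tab)
  expect_equal(tot$ratio, round(tot$predicted_raw / tot$actual_raw, 2))
  expect_gt(tot$ratio, 0.9); expect_lt(tot$ratio, 1.1)
  # doubling predictions doubles the ratio (x2 miscalibration scenario)
  tab2 <- calibration_table(decile_groups(pmin(2 * p_true, 1)),
                            pmin(2 * p_true, 1), times, event, horizon = 5,
                            actual_source = "km")
  expect_equal(expected_and_actual_events(tab2)$ratio, 2 * tot$ratio,
               tolerance = 0.06)
})

test_that("event totals use unrounded ratios at two decimals", {
  mk <- function(p, a) structure(
    data.frame(group = 1, n = 1000, mean_predicted = p, actual = a,
               actual_var = NA, expected_events = 1000 * p,
               actual_events = 1000 * a),
    class = c("calibration_table", "data.frame"))
  out <- expected_and_actual_events(mk(0.302, 0.142))
  expect_equal(out$predicted_events, 302)
  expect_equal(out$actual_events, 142)
  expect_equal(out$ratio, 2.13)
  expect_equal(expected_and_actual_events(mk(0.372, 0.382))$ratio, 0.97)
  expect_true(is.na(expected_and_actual_events(mk(0.1, 0))$ratio))
})
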