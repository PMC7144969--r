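#' Group participants by deciles of predicted risk
#'
#' Empirical-quantile cutpoints; ties at a cutpoint go to the lower group so
#' the assignment is deterministic. Heavy ties can collapse groups: if all
#' risks are identical the single remaining group is returned with a warning.
#'
#' @param risks Numeric predicted-risk vector.
#' @param G Number of groups (default 10); requires `length(risks) >= G`.
#' @return Object of class `decile_assignment`: list with `group` (integer
#'   1..G per participant), `cutpoints` and `G` (the number of non-empty
#'   groups actually formed).
#' @export
decile_groups <- function(risks, G = 10) {
  n <- length(risks)
  if (n < G)
    stop(sprintf("n = %d is smaller than G = %d; use fewer groups", n, G))
  cut_full <- stats::quantile(risks, probs = seq(0, 1, length.out = G + 1),
                              names = FALSE)
  cuts <- unique(cut_full)
  if (length(cuts) < 2) {            # all risks identical
    warning("all predicted risks identical; single degenerate group")
    return(structure(list(group = rep(1L, n), cutpoints = cut_full, G = 1L),
                     class = "decile_assignment"))
  }
  if (length(cuts) < G + 1)
    warning("tied predicted risks collapsed ", G + 1 - length(cuts),
            " group boundary(ies)")
  grp <- cut(risks, breaks = cuts, include.lowest = TRUE, right = TRUE,
             labels = FALSE)
  structure(list(group = as.integer(grp), cutpoints = cut_full,
                 G = length(cuts) - 1L), class = "decile_assignment")
}

#' Per-group calibration table
#'
#' For each risk group, the mean predicted risk is set against the "actual"
#' event probability: the group's own Kaplan-Meier estimate at the horizon
#' (5-year analyses, within observed follow-up), or the grouped Weibull
#' regression projection (10-year analyses, beyond follow-up). Kaplan-Meier
#' uncertainty is the Greenwood interval; Weibull projections get BCa
#' bootstrap intervals when `B > 0` (resampling participants and re-fitting
#' at fixed group membership).
#'
#' @param assignment A `decile_assignment`.
#' @param risks Predicted risks (aligned with `times`).
#' @param times,events Follow-up years and logical CV-event indicators.
#' @param horizon Horizon in years.
#' @param actual_source `"km"` or `"weibull"`.
#' @param B Bootstrap replicates for Weibull projection intervals (0 = none).
#' @param seed Seed for the bootstrap.
#' @param conf Confidence level.
#' @return A data frame of class `calibration_table`: `group`, `n`,
#'   `mean_predicted`, `actual`, `actual_var`, `ci_lower`, `ci_upper`,
#'   `expected_events`, `actual_events`.
#' @export
calibration_table <- function(assignment, risks, times, events, horizon,
                              actual_source = c("km", "weibull"),
                              B = 0, seed = 1, conf = 0.95) {
  actual_source <- match.arg(actual_source)
  grp <- assignment$group
  events <- as.logical(events)
  labels <- sort(unique(grp))
  n_g <- as.vector(table(factor(grp, levels = labels)))
  pbar <- as.vector(tapply(risks, factor(grp, levels = labels), mean))
  z <- stats::qnorm(1 - (1 - conf) / 2)

  if (actual_source == "km") {
    a <- v <- lo <- hi <- numeric(length(labels))
    for (k in seq_along(labels)) {
      i <- grp == labels[k]
      fit <- suppressWarnings(kaplan_meier(times[i], events[i]))
      a[k] <- actual_probability_km(fit, horizon)
      v[k] <- km_variance(fit, horizon)
      lo[k] <- max(0, a[k] - z * sqrt(v[k]))
      hi[k] <- min(1, a[k] + z * sqrt(v[k]))
    }
  } else {
    wfit <- fit_weibull_groups(times, events, grp)
    a <- as.vector(project_probability(wfit, horizon, group = labels))
    v <- rep(NA_real_, length(labels))
    lo <- hi <- rep(NA_real_, length(labels))
    if (B > 0) {
      boot_proj <- function(idx) {
        f <- suppressWarnings(fit_weibull_groups(times[idx], events[idx], grp[idx]))
        out <- rep(NA_real_, length(labels))
        out[match(f$group_labels, labels)] <-
          project_probability(f, horizon, group = f$group_labels)
        out
      }
      set.seed(seed)
      bs <- replicate(B, boot_proj(sample.int(length(times), replace = TRUE)))
      jk <- vapply(seq_along(times),
                   function(i) boot_proj(seq_along(times)[-i]),
                   numeric(length(labels)))
      for (k in seq_along(labels)) {
        ci <- bca_interval(a[k], bs[k, ], jk[k, ], conf = conf)
        lo[k] <- ci[1]; hi[k] <- ci[2]
        v[k] <- stats::var(bs[k, ], na.rm = TRUE)
      }
    }
  }
  structure(data.frame(group = labels, n = n_g, mean_predicted = pbar,
                       actual = a, actual_var = v,
                       ci_lower = lo, ci_upper = hi,
                       expected_events = n_g * pbar,
                       actual_events = n_g * a),
            horizon = horizon, actual_source = actual_source,
            class = c("calibration_table", "data.frame"))
}

#' Calibration-in-the-large: expected and actual event totals
#'
#' Sums expected (`n_g * mean predicted risk`) and actual (`n_g * actual
#' probability`) events across groups. Totals are rounded to integers for
#' display; the predicted/actual ratio is computed on the unrounded totals
#' and reported to 2 decimals.
#'
#' @param table A `calibration_table`.
#' @return List with `predicted_events`, `actual_events` (rounded),
#'   `predicted_raw`, `actual_raw`, `ratio` (2 dp; `NA` when no actual
#'   events).
#' @export
expected_and_actual_events <- function(table) {
  pred <- sum(table$expected_events)
  act <- sum(table$actual_events)
  list(predicted_events = round(pred), actual_events = round(act),
       predicted_raw = pred, actual_raw = act,
       ratio = if (act == 0) NA_real_ else round(pred / act, 2))
}

#' Nam-D'Agostino chi-square calibration test
#'
#' Grouped goodness-of-calibration statistic for survival risk models:
#' `chi^2 = sum_g n_g (a_g - pbar_g)^2 / (pbar_g (1 - pbar_g))` with the
#' external-validation convention of `df = G` degrees of freedom (no
#' parameters were estimated on the validation data; the df convention is
#' surfaced in the output rather than hidden). A Greenwood-variance variant
#' divides by `Var(a_g)` instead.
#'
#' @param table A `calibration_table`.
#' @param variance `"binomial"` (default) or `"greenwood"` (requires
#'   `actual_var` in the table).
#' @return List with `chi_square`, `df`, `p_value` and `variance`.
#' @export
nam_dagostino <- function(table, variance = c("binomial", "greenwood")) {
  variance <- match.arg(variance)
  p <- table$mean_predicted; a <- table$actual; n <- table$n
  drop <- p <= 0 | p >= 1
  if (any(drop)) {
    warning(sum(drop), " group(s) with degenerate mean predicted risk excluded; df reduced")
    p <- p[!drop]; a <- a[!drop]; n <- n[!drop]
  }
  terms <- if (variance == "binomial") {
    n * (a - p)^2 / (p * (1 - p))
  } else {
    v <- table$actual_var[!drop]
    if (any(is.na(v) | v <= 0)) stop("Greenwood variant needs positive actual_var")
    (a - p)^2 / v
  }
  chi2 <- sum(terms); df <- length(p)
  list(chi_square = chi2, df = df,
       p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
       variance = variance)
}

#' Harrell's concordance index for right-censored data
#'
#' Probability that, of a comparable pair, the participant with the earlier
#' event carries the higher predicted risk. An observation serves as the
#' pair's reference if it has an event and either a strictly earlier time, or
#' an equal time with the other observation censored; tied event times are
#' incomparable, and tied risks score half. The O(n^2) pair scan runs in
#' compiled code.
#'
#' @param times,events Follow-up years and logical event indicators.
#' @param risks Predicted risks.
#' @return Concordance in \[0, 1\].
#' @export
harrell_c <- function(times, events, risks) {
  stopifnot(length(times) == length(events), length(times) == length(risks))
  cc <- concordance_counts(as.numeric(times), as.logical(events),
                           as.numeric(risks))
  if (cc$comparable == 0) stop("no comparable pairs; concordance undefined")
  cc$concordant / cc$comparable
}

#' Leave-one-out concordance values
#'
#' All n jackknife values of [harrell_c()] from a single O(n^2) pass: each
#' pair's credit is attributed to both members, so removing observation i
#' subtracts its concordant and comparable sums.
#'
#' @inheritParams harrell_c
#' @return Numeric vector of n leave-one-out concordance values.
#' @export
harrell_c_jackknife <- function(times, events, risks) {
  cc <- concordance_counts(as.numeric(times), as.logical(events),
                           as.numeric(risks))
  denom <- cc$comparable - cc$comparable_by_obs
  if (any(denom == 0)) stop("a leave-one-out sample has no comparable pairs")
  (cc$concordant - cc$concordant_by_obs) / denom
}

# Core BCa interval given a point estimate, bootstrap replicates and
# jackknife values of the statistic.
bca_interval <- function(t0, boot_stats, jack_stats, conf = 0.95) {
  boot_stats <- boot_stats[!is.na(boot_stats)]
  prop <- mean(boot_stats < t0)
  if (prop == 0 || prop == 1)   # degenerate bootstrap distribution
    return(stats::quantile(boot_stats, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                           names = FALSE))
  z0 <- stats::qnorm(prop)
  jm <- mean(jack_stats)
  num <- sum((jm - jack_stats)^3)
  den <- 6 * sum((jm - jack_stats)^2)^1.5
  a <- if (den == 0) 0 else num / den
  zq <- stats::qnorm(c((1 - conf) / 2, 1 - (1 - conf) / 2))
  adj <- stats::pnorm(z0 + (z0 + zq) / (1 - a * (z0 + zq)))
  stats::quantile(boot_stats, adj, names = FALSE)
}

#' Bias-corrected and accelerated (BCa) bootstrap interval
#'
#' Nonparametric bootstrap at the participant level. The bias correction
#' `z0` comes from the share of bootstrap replicates below the point
#' estimate; the acceleration `a` from the jackknife third-moment formula.
#' Deterministic given `seed`.
#'
#' @param data A vector, or a data frame resampled by rows.
#' @param statistic Function of one resample returning a scalar.
#' @param B Number of bootstrap replicates (>= 200; 2,000 in the validation
#'   pipeline).
#' @param seed Integer seed.
#' @param conf Confidence level.
#' @param jackknife_values Optional precomputed leave-one-out statistic
#'   values (e.g. from [harrell_c_jackknife()]); otherwise the generic
#'   jackknife evaluates `statistic` n times.
#' @return List with `estimate`, `ci_lower`, `ci_upper`, `B`, `conf`.
#' @export
bca_bootstrap <- function(data, statistic, B = 2000, seed = 1, conf = 0.95,
                          jackknife_values = NULL) {
  if (B < 200) stop("B must be at least 200")
  n <- if (is.data.frame(data)) nrow(data) else length(data)
  take <- if (is.data.frame(data)) function(i) data[i, , drop = FALSE]
          else function(i) data[i]
  t0 <- statistic(data)
  set.seed(seed)
  boot_stats <- vapply(seq_len(B), function(b) {
    idx <- sample.int(n, replace = TRUE)
    tryCatch(statistic(take(idx)), error = function(e) NA_real_)
  }, numeric(1))
  n_fail <- sum(is.na(boot_stats))
  if (n_fail > 0.01 * B)
    stop(sprintf("statistic failed on %d of %d resamples", n_fail, B))
  if (is.null(jackknife_values))
    jackknife_values <- vapply(seq_len(n),
                               function(i) statistic(take(-i)), numeric(1))
  ci <- bca_interval(t0, boot_stats, jackknife_values, conf = conf)
  list(estimate = t0, ci_lower = ci[1], ci_upper = ci[2], B = B, conf = conf)
}
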