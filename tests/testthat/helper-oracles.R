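# Independent reference implementations used as oracles. These deliberately
# share no code with the package internals they check.

# O(n^2) concordance by exhaustive pair enumeration. Each unordered pair has
# at most one usable reference (the earlier event, or the event at a tied
# time with the other censored), so scanning ordered pairs counts each
# comparable pair exactly once.
harrell_c_reference <- function(times, events, risks) {
  n <- length(times)
  conc <- 0; comp <- 0
  for (i in seq_len(n)) {
    if (!events[i]) next
    for (j in seq_len(n)) {
      if (i == j) next
      usable <- times[i] < times[j] || (times[i] == times[j] && !events[j])
      if (!usable) next
      comp <- comp + 1
      conc <- conc + (risks[i] > risks[j]) + 0.5 * (risks[i] == risks[j])
    }
  }
  if (comp == 0) stop("no comparable pairs")
  conc / comp
}

# Hand product-limit estimator evaluated at a single time.
km_reference <- function(times, events, t) {
  s <- 1
  for (u in sort(unique(times[events]))) {
    if (u > t) break
    d <- sum(times == u & events)
    n_at_risk <- sum(times >= u)
    s <- s * (1 - d / n_at_risk)
  }
  s
}

# Direct numeric maximisation of the right-censored Weibull likelihood.
weibull_mle_reference <- function(times, events) {
  nll <- function(par) {
    shape <- exp(par[1]); scale <- exp(par[2])
    -sum(ifelse(events,
                dweibull(times, shape, scale, log = TRUE),
                pweibull(times, shape, scale, lower.tail = FALSE, log.p = TRUE)))
  }
  fit <- optim(c(0, log(mean(times))), nll)
  c(shape = exp(fit$par[1]), scale = exp(fit$par[2]))
}

# Small toy cause model with convenient closed forms.
toy_cause_model <- function(alpha = -5, p = 2, betas = c(sbp = 0.02),
                            centering = c(sbp = 120), age_origin = 20) {
  weibull_cause_model(alpha = alpha, p = p, betas = betas,
                      centering = centering, age_origin = age_origin)
}

# A complete single-profile list for the SCORE OP-style models.
toy_profile <- function(age = 75, sex = "male", sbp = 140, total_chol = 5.5,
                        hdl_chol = 1.4, smoker = FALSE, diabetes = FALSE) {
  list(age = age, sex = sex, sbp = sbp, total_chol = total_chol,
       hdl_chol = hdl_chol, smoker = smoker, diabetes = diabetes)
}

# Write a small cohort CSV in the default dialect and return its path.
write_fixture_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE, na = "")
  path
}

default_header_df <- function(n = 3) {
  data.frame(id = paste0("p", seq_len(n)), age = 75 + seq_len(n),
             sex = rep(c("M", "F"), length.out = n), sbp = 140 + seq_len(n),
             tc = 5 + 0.1 * seq_len(n), hdl = 1.2 + 0.05 * seq_len(n),
             smoker = 0, diabetes = 0, antihtn = 1, prior_mi = "no",
             fu_years = seq_len(n), status = 0, cause = "NA",
             stringsAsFactors = FALSE)
}
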