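# Shared fixture builders: everything is generated in code at test time.

# Minimal hand-written cohort: 3 subjects x 2 analytes.
make_toy_cohort <- function() {
  cohort_table(
    subjects = data.frame(
      subject_id = c("s1", "s2", "s3"),
      age_at_lp = c(70, 75, 80),
      gender = c("female", "male", "female"),
      apoe = c("e3e3", "e3e4", "e2e3"),
      cdr = c(0, 0, 0.5),
      stringsAsFactors = FALSE),
    analytes = matrix(c(10, 20, 30, 1.5, 2.5, 3.5), nrow = 3,
                      dimnames = list(NULL, c("m1", "m2"))),
    analyte_meta = data.frame(analyte = c("m1", "m2"),
                              unit = c("pg/mL", "ng/mL"),
                              ldl = c(1, 0.1), stringsAsFactors = FALSE))
}

# Clean simulated cohort on the analysis scale (no censoring/missingness),
# small enough for fast unit tests.
make_clean_cohort <- function(seed = 1, n_per_group = c(120, 30, 15),
                              n_analytes = 12, n_signal = min(3, n_analytes),
                              traditional = FALSE) {
  sc <- sim_scenario(n_per_group = n_per_group, n_analytes = n_analytes,
                     n_signal = n_signal, missing_rate = 0,
                     outlier_rate = 0, ldl_quantile = 0,
                     traditional = traditional)
  generate_cohort(sc, seed)
}

# Direct two-group binormal sample with known truth (no cohort plumbing).
make_binormal_sample <- function(n0, n1, mu0, mu1, sigma, seed = 1) {
  set.seed(seed)
  d <- length(mu0)
  ch <- chol(sigma)
  x0 <- matrix(rnorm(n0 * d), n0, d) %*% ch + rep(mu0, each = n0)
  x1 <- matrix(rnorm(n1 * d), n1, d) %*% ch + rep(mu1, each = n1)
  colnames(x0) <- colnames(x1) <- paste0("m", seq_len(d))
  list(x = rbind(x0, x1),
       labels = factor(rep(c("ctrl", "case"), c(n0, n1)),
                       levels = c("ctrl", "case")))
}

# Exact Cox partial likelihood for untied data (brute-force oracle).
exact_cox_loglik <- function(beta, time, event, x) {
  eta <- as.numeric(as.matrix(x) %*% beta)
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + eta[i] - log(sum(exp(eta[risk])))
  }
  ll
}
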