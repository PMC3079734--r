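test_that("empirical AUC matches the exhaustive pair count", {
  lab <- rep(c(0, 1), each = 5)
  expect_equal(empirical_auc(c(1:5, 6:10), lab)$auc, 1.0)
  expect_equal(empirical_auc(rep(3.3, 10), lab)$auc, 0.5)
  s <- c(0.2, 0.9, 0.4, 0.4, 0.7, 0.3, 0.4, 0.8, 0.9, 0.6)
  a <- empirical_auc(s, lab)
  ctrl <- s[1:5]; case <- s[6:10]
  oracle <- (sum(outer(case, ctrl, ">")) +
               0.5 * sum(outer(case, ctrl, "=="))) / 25
  expect_equal(a$auc, oracle)
  expect_equal(a$auc_oriented, max(oracle, 1 - oracle))
  expect_error(empirical_auc(1:5, rep(1, 5)), "both classes")
})

test_that("binormal fit stores group moments exactly", {
  # single marker with group stats mirroring established tau levels
  m <- fit_binormal(
    matrix(c(315, 315 - 169, 315 + 169, 547, 547 - 278, 547 + 278),
           ncol = 1, dimnames = list(NULL, "tau")),
    rep(c(0, 1), each = 3))
  expect_equal(unname(m$mu0), 315)
  expect_equal(unname(m$mu1), 547)
  expect_equal(as.numeric(m$sigma0), 169^2)
  expect_equal(as.numeric(m$sigma1), 278^2)
  # analytic AUC for a single marker: pnorm(|delta| / sqrt(v0 + v1))
  expect_equal(m$auc, pnorm(232 / sqrt(169^2 + 278^2)), tolerance = 1e-12)
  expect_equal(round(m$auc, 2), 0.76)
})

test_that("two identical groups give a zero separation and AUC 0.5", {
  x <- matrix(rnorm(40), ncol = 2, dimnames = list(NULL, c("a", "b")))
  m <- fit_binormal(rbind(x, x), rep(c(0, 1), each = 20))
  expect_equal(unname(m$mu1 - m$mu0), c(0, 0), tolerance = 1e-12)
  expect_equal(m$auc, 0.5)
})

test_that("sample moments on a 6-subject toy match direct arithmetic", {
  x <- matrix(c(1, 2, 3, 10, 11, 15, 2, 4, 9, 3, 8, 1), ncol = 2,
              dimnames = list(NULL, c("a", "b")))
  y <- c(0, 0, 0, 1, 1, 1)
  m <- fit_binormal(x, y, strict = TRUE)
  expect_equal(unname(m$mu0), c(2, 5))
  expect_equal(unname(m$mu1), c(12, 4))
  expect_equal(m$sigma0, cov(x[1:3, ]), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(m$sigma1, cov(x[4:6, ]), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("symmetric two-marker case forces the equal-weight combination", {
  m <- csfpanels:::new_binormal_model(c("a", "b"), c(0, 0), c(1, 1),
                                      diag(2), diag(2))
  expect_equal(unname(m$a), c(1, 1) / sqrt(2), tolerance = 1e-12)
  expect_equal(m$auc, pnorm(1), tolerance = 1e-12)
})

test_that("closed-form combination dominates random directions", {
  set.seed(20)
  for (d in 2:4) {
    A <- matrix(rnorm(d * d), d)
    s0 <- crossprod(A) + diag(d) * 0.1
    B <- matrix(rnorm(d * d), d)
    s1 <- crossprod(B) + diag(d) * 0.1
    m <- csfpanels:::new_binormal_model(paste0("m", 1:d), rnorm(d),
                                        rnorm(d, 0.5), s0, s1)
    U <- matrix(rnorm(2000 * d), 2000)
    U <- U / sqrt(rowSums(U^2))
    rand_auc <- apply(U, 1, function(u) combination_auc(m, u))
    expect_gte(m$auc, max(rand_auc) - 1e-9)
    # and the fitted coefficient direction attains the optimum
    expect_equal(combination_auc(m, m$a), m$auc, tolerance = 1e-12)
  }
})

test_that("adding a marker never decreases the in-sample analytic AUC", {
  set.seed(21)
  for (rep in 1:10) {
    smp <- make_binormal_sample(60, 40, rnorm(3), rnorm(3, 0.3),
                                crossprod(matrix(rnorm(9), 3)) + diag(3),
                                seed = rep)
    auc2 <- fit_binormal(smp$x[, 1:2], smp$labels)$auc
    auc3 <- fit_binormal(smp$x, smp$labels)$auc
    expect_gte(auc3, auc2 - 1e-12)
  }
})

test_that("binormal sensitivity behaves at the identical-group and strong limits", {
  same <- csfpanels:::new_binormal_model("a", 1, 1, 4, 4)
  expect_equal(sensitivity_at_specificity(same, 0.80), 0.20,
               tolerance = 1e-12)
  strong <- csfpanels:::new_binormal_model("a", 0, 100, 1, 1)
  expect_gt(sensitivity_at_specificity(strong, 0.80), 0.999)
  expect_error(sensitivity_at_specificity(same, 1.2), "specificity")
})

test_that("binormal formulas agree with Monte-Carlo at large n", {
  sigma <- matrix(c(1, 0.4, 0.4, 1.5), 2)
  mu0 <- c(0, 0); mu1 <- c(0.8, 0.5)
  truth <- csfpanels:::new_binormal_model(c("m1", "m2"), mu0, mu1,
                                          sigma, sigma)
  smp <- make_binormal_sample(50000, 50000, mu0, mu1, sigma, seed = 22)
  scores <- panel_scores(truth, smp$x)
  emp_auc <- empirical_auc(scores, smp$labels)$auc
  expect_lt(abs(emp_auc - truth$auc), 0.01)
  emp_sens <- sensitivity_at_specificity(scores, 0.80, labels = smp$labels)
  bin_sens <- sensitivity_at_specificity(truth, 0.80)
  expect_lt(abs(emp_sens - bin_sens), 0.005)
})

test_that("empirical and fitted analytic AUC converge on binormal data", {
  sigma <- matrix(c(1, 0.3, 0.3, 1), 2)
  smp <- make_binormal_sample(5000, 5000, c(0, 0), c(0.7, 0.3), sigma,
                              seed = 23)
  m <- fit_binormal(smp$x, smp$labels)
  emp <- empirical_auc(panel_scores(m, smp$x), smp$labels)$auc
  expect_lt(abs(emp - m$auc), 0.01)
})

test_that("panel expansion skips duplicates deterministically", {
  bases <- list(c("ratio", "cysC"), c("ratio", "VEGF"), c("ratio", "KIM1"),
                c("ratio", "PP"))
  cands <- c("TRAILR3", "PAI1", "PP", "NTproBNP", "MMP10", "MIF", "GROa",
             "fibrinogen", "FAS", "eotaxin3")
  panels <- expand_panels(bases, cands, 4, 10)
  expect_length(panels, 39)             # one candidate sits inside one base
  expect_identical(panels[[1]], c("ratio", "cysC", "TRAILR3"))
  expect_length(expand_panels(list(c("a", "b")), "c", 1, 1), 1)
  expect_length(expand_panels(list(c("a", "b")), c("a", "b"), 1, 2), 0)
  expect_warning(expand_panels(list(c("a", "b")), "c", 4, 1), "base panels")
})

test_that("bootstrap evaluation is reproducible and handles nesting limits", {
  smp <- make_binormal_sample(80, 40, c(0, 0, 0), c(0.9, 0.5, 0.3),
                              diag(3), seed = 24)
  e1 <- bootstrap_evaluate(smp$x, smp$labels, c("m1", "m2", "m3"),
                           c("m1", "m2"), B = 25, seed = 7)
  e2 <- bootstrap_evaluate(smp$x, smp$labels, c("m1", "m2", "m3"),
                           c("m1", "m2"), B = 25, seed = 7)
  expect_identical(e1$iterations, e2$iterations)
  expect_true(e1$auc[["ci_lo"]] <= e1$auc[["mean"]],
              e1$auc[["mean"]] <= e1$auc[["ci_hi"]])
  # reduced == panel: delta AUC degenerate, p defined as 1
  same <- bootstrap_evaluate(smp$x, smp$labels, c("m1", "m2"),
                             c("m1", "m2"), B = 5, seed = 7)
  expect_true(all(same$iterations$p_value == 1))
  expect_error(bootstrap_evaluate(smp$x, smp$labels, c("m1", "m2"),
                                  c("m1", "m3"), B = 5), "nested")
  expect_error(bootstrap_evaluate(smp$x, smp$labels, c("m1", "m2"),
                                  c("m1"), B = 1), "B must be")
})

test_that("bootstrap-mean AUC recovers a strong constructed signal", {
  # two markers built so the true optimal-combination AUC is 0.90
  target_q <- qnorm(0.90)^2         # delta' (sigma0 + sigma1)^-1 delta
  delta <- c(1, 1) * sqrt(target_q / 2)  # per-group Sigma = I/2, so sum = I
  sigma <- diag(2) / 2
  truth <- csfpanels:::new_binormal_model(c("m1", "m2"), c(0, 0), delta,
                                          sigma, sigma)
  expect_equal(truth$auc, 0.90, tolerance = 1e-12)
  smp <- make_binormal_sample(242, 91, c(0, 0), delta, sigma, seed = 25)
  ev <- bootstrap_evaluate(smp$x, smp$labels, c("m1", "m2"), "m1",
                           B = 100, seed = 8)
  expect_lt(abs(ev$auc[["mean"]] - 0.90), 0.03)
})

test_that("no-signal panels evaluate near chance with non-small p-values", {
  means <- ps <- numeric(5)
  for (s in 1:5) {
    smp <- make_binormal_sample(242, 91, c(0, 0, 0), c(0, 0, 0), diag(3),
                                seed = 100 + s)
    ev <- bootstrap_evaluate(smp$x, smp$labels, c("m1", "m2", "m3"),
                             c("m1", "m2"), B = 40, seed = s)
    means[s] <- ev$auc[["mean"]]
    ps[s] <- ev$p_value[["mean"]]
  }
  expect_true(all(means > 0.45 & means < 0.60))
  expect_gt(mean(ps), 0.2)
})

test_that("ratio markers are derived before transformation and logged after", {
  gen <- make_clean_cohort(seed = 26, n_per_group = c(60, 15, 8),
                           n_analytes = 4, traditional = TRUE)
  qc <- qc_pipeline(gen$cohort)
  withr <- add_ratio_marker(qc$cohort, "tau", "abeta42")
  expect_true("tau_over_abeta42" %in% colnames(withr$analytes))
  expect_equal(withr$analytes[, "tau_over_abeta42"],
               qc$cohort$analytes[, "tau"] / qc$cohort$analytes[, "abeta42"])
  expect_true(withr$analyte_meta$lognormal[
    withr$analyte_meta$analyte == "tau_over_abeta42"])
})
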