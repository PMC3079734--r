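test_that("Youden index reproduces published printed rows and edge cases", {
  # two representative printed sensitivity/specificity pairs
  expect_equal(round(youden_index(0.845, 0.776), 3), 0.621)
  expect_equal(round(youden_index(0.872, 0.566), 3), 0.438)
  expect_equal(youden_index(1, 1), 1)
  expect_equal(youden_index(0.5, 0.5), 0)
  expect_error(youden_index(1.2, 0.5), "0, 1")
})

test_that("oracle and constant classifiers bound the harness", {
  gen <- make_clean_cohort(seed = 30, n_per_group = c(60, 20, 10),
                           n_analytes = 3)
  x <- build_predictors(gen$cohort, colnames(gen$cohort$analytes))
  y <- cdr_group(gen$cohort)
  # the oracle reads the truth from an extra predictor column
  x_or <- cbind(x, truth = as.numeric(y == "cdr_gt0"))
  oracle <- make_classifier("oracle",
                            fit = function(x, y) list(),
                            predict = function(m, x) x[, "truth"])
  r <- resample_evaluate(oracle, x_or, y, n_splits = 10, seed = 31)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  expect_equal(r$youden, 1)
  const <- make_classifier("const",
                           fit = function(x, y) list(),
                           predict = function(m, x) rep(0.5, nrow(x)))
  rc <- resample_evaluate(const, x, y, n_splits = 10, seed = 31)
  expect_equal(rc$auc, 0.5)          # all ties
  expect_equal(rc$youden, 0)         # sens 1, spec 0 at the 0.5 cut
})

test_that("seeded harness runs are identical and splits are stratified", {
  gen <- make_clean_cohort(seed = 32, n_per_group = c(60, 20, 10),
                           n_analytes = 3)
  x <- build_predictors(gen$cohort, colnames(gen$cohort$analytes))
  y <- cdr_group(gen$cohort)
  r1 <- resample_evaluate(classifier_gnb(), x, y, n_splits = 15, seed = 33)
  r2 <- resample_evaluate(classifier_gnb(), x, y, n_splits = 15, seed = 33)
  expect_identical(r1$per_split, r2$per_split)
  # Youden identity holds on every emitted row
  expect_equal(r1$per_split$youden,
               r1$per_split$sensitivity + r1$per_split$specificity - 1)
  # stratified split preserves the class ratio within one subject
  set.seed(34)
  sp <- csfpanels:::stratified_split(y, 0.8)
  ratio_all <- mean(y == "cdr_gt0")
  n_tr <- length(sp$train)
  expect_lte(abs(sum(y[sp$train] == "cdr_gt0") - ratio_all * n_tr), 1)
})

test_that("classifier failures on splits are excluded and counted", {
  gen <- make_clean_cohort(seed = 35, n_per_group = c(40, 12, 6),
                           n_analytes = 2)
  x <- build_predictors(gen$cohort, colnames(gen$cohort$analytes))
  y <- cdr_group(gen$cohort)
  flaky_state <- new.env()
  flaky_state$i <- 0
  flaky <- make_classifier("flaky",
                           fit = function(x, y) {
                             flaky_state$i <- flaky_state$i + 1
                             if (flaky_state$i %% 3 == 0) stop("boom")
                             list()
                           },
                           predict = function(m, x) runif(nrow(x)))
  r <- resample_evaluate(flaky, x, y, n_splits = 9, seed = 36)
  expect_equal(r$n_failed, 3)
  expect_equal(nrow(r$per_split), 6)
})

test_that("NSC at zero threshold equals plain nearest-centroid classification", {
  set.seed(37)
  x <- matrix(rnorm(60 * 4), 60, 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  y <- factor(rep(c("a", "b"), each = 30))   # equal priors
  x[y == "b", 1:2] <- x[y == "b", 1:2] + 1.5
  m <- nsc_fit(x, y, threshold = 0)
  sc <- nsc_predict(m, x)
  # oracle: assign to the nearer centroid in (s + s0)-standardized distance
  cent_a <- colMeans(x[y == "a", ]); cent_b <- colMeans(x[y == "b", ])
  sd_pool <- sqrt((colSums((x[y == "a", ] - rep(cent_a, each = 30))^2) +
                   colSums((x[y == "b", ] - rep(cent_b, each = 30))^2)) / 58)
  s0 <- median(sd_pool)
  d_a <- rowSums(((x - rep(cent_a, each = 60)) / rep(sd_pool + s0, each = 60))^2)
  d_b <- rowSums(((x - rep(cent_b, each = 60)) / rep(sd_pool + s0, each = 60))^2)
  expect_identical(sc > 0.5, d_b < d_a)
})

test_that("full shrinkage collapses predictions to the class priors", {
  set.seed(38)
  x <- matrix(rnorm(50 * 3), 50, 3, dimnames = list(NULL, paste0("f", 1:3)))
  y <- factor(rep(c("a", "b"), c(20, 30)))
  m <- nsc_fit(x, y, threshold = 1e6)
  expect_true(all(abs(m$d_shrunk) == 0))
  sc <- nsc_predict(m, x)
  expect_equal(sc, rep(sc[1], 50))   # identical score for every subject
  expect_equal(nsc_predict(m, x[1, , drop = FALSE]) > 0.5,
               unname(m$prior[2] > m$prior[1]))
  expect_error(nsc_fit(x, y, threshold = -1), ">= 0")
})

test_that("shrunken centroids match the soft-threshold formula on a toy", {
  x <- matrix(c(1, 2, 3, 4, 10, 11, 12, 13,
                5, 5, 6, 6, 7, 7, 8, 8,
                0, 1, 0, 1, 0, 1, 0, 1), 8, 3,
              dimnames = list(NULL, c("f1", "f2", "f3")))
  y <- factor(rep(c("a", "b"), each = 4))
  thr <- 1.0
  m <- nsc_fit(x, y, thr)
  # direct formula
  n <- 8; nk <- c(4, 4)
  xbar <- colMeans(x)
  cent <- rbind(colMeans(x[1:4, ]), colMeans(x[5:8, ]))
  s <- sqrt((colSums((x[1:4, ] - rep(cent[1, ], each = 4))^2) +
             colSums((x[5:8, ] - rep(cent[2, ], each = 4))^2)) / (n - 2))
  s0 <- median(s)
  for (k in 1:2) {
    mk <- sqrt(1 / nk[k] - 1 / n)
    d <- (cent[k, ] - xbar) / (mk * (s + s0))
    d_shr <- sign(d) * pmax(abs(d) - thr, 0)
    expect_equal(unname(m$centroids[k, ]),
                 unname(xbar + mk * (s + s0) * d_shr), tolerance = 1e-12)
  }
})

test_that("NSC importance ranks surviving features by shrunken difference", {
  set.seed(39)
  x <- matrix(rnorm(80 * 5), 80, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- factor(rep(c("a", "b"), each = 40))
  x[y == "b", 2] <- x[y == "b", 2] + 3    # f2 is the real signal
  m <- nsc_fit(x, y, threshold = 0.5)
  imp <- nsc_importance(m)
  expect_equal(names(imp)[1], "f2")
  expect_true(all(diff(unname(imp)) <= 0))
})

test_that("k-NN has perfect training recall at k = 1 and validates k", {
  set.seed(40)
  x <- matrix(rnorm(30 * 3), 30, 3, dimnames = list(NULL, paste0("f", 1:3)))
  y <- factor(sample(c("a", "b"), 30, replace = TRUE))
  m <- knn_fit(x, y, k = 1)
  sc <- knn_predict(m, x)
  expect_identical(sc > 0.5, y == "b")
  expect_error(knn_fit(x, y, k = 31), "exceeds")
})

test_that("Gaussian naive Bayes matches the closed-form posterior", {
  set.seed(41)
  x <- matrix(c(rnorm(50, 0, 1), rnorm(50, 2, 1)), ncol = 1,
              dimnames = list(NULL, "f1"))
  y <- factor(rep(c("a", "b"), each = 50))
  m <- gnb_fit(x, y)
  xt <- matrix(seq(-2, 4, 0.5), ncol = 1, dimnames = list(NULL, "f1"))
  sc <- gnb_predict(m, xt)
  p <- m$pars
  lik_a <- dnorm(xt[, 1], p$a$mean, p$a$sd) * 0.5
  lik_b <- dnorm(xt[, 1], p$b$mean, p$b$sd) * 0.5
  expect_equal(sc, lik_b / (lik_a + lik_b), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("kernel naive Bayes tends to the priors as bandwidth grows", {
  set.seed(42)
  x <- matrix(rnorm(60), ncol = 1, dimnames = list(NULL, "f1"))
  y <- factor(rep(c("a", "b"), c(20, 40)))
  m <- gnb_fit(x, y, kernel = TRUE, bandwidth = 1e6)
  sc <- gnb_predict(m, x)
  expect_equal(sc, rep(2 / 3, 60), tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("importance overlap counts match exhaustive set arithmetic", {
  r <- list(m1 = c("a", "b", "c", "d"),
            m2 = c("a", "c", "e", "f"),
            m3 = c("g", "a", "h", "b"))
  ov <- importance_overlap(r, k = 4, reference_set = c("a", "e", "z"))
  expect_equal(ov$pairwise["m1", "m2"], 2L)   # {a, c}
  expect_equal(ov$pairwise["m1", "m3"], 2L)   # {a, b}
  expect_equal(ov$pairwise["m2", "m3"], 1L)   # {a}
  expect_equal(ov$global, 1L)
  expect_equal(unname(ov$reference_overlap), c(1L, 2L, 1L))
  ident <- importance_overlap(list(x = letters[1:15], y = letters[1:15]))
  expect_equal(ident$global, 15L)
  disj <- importance_overlap(list(x = letters[1:4], y = letters[5:8]), k = 4)
  expect_equal(disj$global, 0L)
  expect_error(importance_overlap(list(x = letters[1:3]), k = 3), ">= 2")
  expect_error(importance_overlap(r, k = 10), "shorter")
})

test_that("adding informative analytes raises NSC Youden over seeds", {
  # directional property: the richer predictor set should not do worse
  youden_gain <- vapply(1:8, function(s) {
    gen <- make_clean_cohort(seed = 200 + s, n_per_group = c(90, 25, 12),
                             n_analytes = 8, n_signal = 4,
                             traditional = TRUE)
    qc <- qc_pipeline(gen$cohort)
    tr <- apply_transforms(qc$cohort, qc$transforms)
    y <- cdr_group(tr)
    nsc <- classifier_nsc(threshold_grid = 1.0)   # fixed threshold
    trad <- resample_evaluate(
      nsc, build_predictors(tr, c("tau", "abeta42", "ptau181")), y,
      n_splits = 15, seed = s)
    both <- resample_evaluate(
      nsc, build_predictors(tr, colnames(tr$analytes)), y,
      n_splits = 15, seed = s)
    both$youden - trad$youden
  }, numeric(1))
  expect_gte(mean(youden_gain > -0.02), 0.75)
})

test_that("external learners attach through the adapter contract", {
  skip_if_not_installed("randomForest")
  gen <- make_clean_cohort(seed = 43, n_per_group = c(60, 20, 10),
                           n_analytes = 4, n_signal = 2)
  x <- build_predictors(gen$cohort, colnames(gen$cohort$analytes))
  y <- cdr_group(gen$cohort)
  rf <- make_classifier(
    "rf",
    fit = function(x, y) randomForest::randomForest(x, y, ntree = 100),
    predict = function(m, x) predict(m, x, type = "prob")[, 2])
  r <- resample_evaluate(rf, x, y, n_splits = 5, seed = 44)
  expect_true(r$auc > 0.5)
  expect_equal(r$youden, r$sensitivity + r$specificity - 1)
})
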