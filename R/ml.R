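#' Youden index
#'
#' \code{J = sensitivity + specificity - 1}; the summary statistic used to
#' compare classifiers at their operating point.
#' @param sensitivity,specificity values in [0, 1].
#' @return J in [-1, 1].
#' @export
youden_index <- function(sensitivity, specificity) {
  if (any(sensitivity < 0 | sensitivity > 1, na.rm = TRUE) ||
      any(specificity < 0 | specificity > 1, na.rm = TRUE)) {
    stop("youden_index: inputs must lie in [0, 1]")
  }
  sensitivity + specificity - 1
}

#' Define a classifier for the resampling harness
#'
#' The fit/score contract every learner (native or external adapter) must
#' satisfy: \code{fit(x, y)} receives a numeric matrix and a two-level factor
#' (second level = positive class) and returns any model object;
#' \code{predict(model, x)} returns positive-class scores in [0, 1]. Any
#' hyperparameter tuning must happen inside \code{fit} using only the
#' training split it is given.
#'
#' @param name display name.
#' @param fit function(x, y) -> model.
#' @param predict function(model, x) -> numeric scores.
#' @param importance optional function(model) -> named numeric importance
#'   scores (larger = more important).
#' @return object of class \code{csf_classifier}.
#' @export
make_classifier <- function(name, fit, predict, importance = NULL) {
  stopifnot(is.function(fit), is.function(predict))
  structure(list(name = name, fit = fit, predict = predict,
                 importance = importance),
            class = "csf_classifier")
}

# ---- nearest shrunken centroids (native) ----------------------------------

#' Fit a nearest shrunken centroids model
#'
#' Class centroids are shrunk toward the overall centroid by soft-thresholding
#' the standardized centroid differences at \code{threshold}: with pooled
#' within-class SD \code{s_i} (offset by \code{s0 = median(s_i)}) and
#' \code{m_k = sqrt(1/n_k - 1/n)}, the standardized difference \code{d_ik =
#' (xbar_ik - xbar_i) / (m_k (s_i + s0))} becomes \code{sign(d)(|d| -
#' threshold)+}, and the shrunken centroid is \code{xbar_i + m_k (s_i + s0)
#' d'_ik}. Prediction uses the discriminant score \code{sum((x - xbar'_k)^2 /
#' (s + s0)^2) - 2 log(prior_k)}. At threshold 0 this is plain
#' nearest-centroid classification; features whose differences are fully
#' shrunk drop out, giving built-in feature selection.
#'
#' @param x numeric matrix (rows = subjects).
#' @param y two-level factor; second level = positive class.
#' @param threshold shrinkage threshold (>= 0).
#' @return object of class \code{nsc_model}.
#' @export
nsc_fit <- function(x, y, threshold) {
  if (threshold < 0) stop("nsc_fit: threshold must be >= 0")
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  K <- nlevels(y)
  n <- nrow(x)
  nk <- table(y)
  xbar <- colMeans(x)
  cent <- t(vapply(levels(y), function(l) colMeans(x[y == l, , drop = FALSE]),
                   numeric(ncol(x))))
  ss <- 0
  for (l in levels(y)) {
    xi <- x[y == l, , drop = FALSE]
    ss <- ss + colSums((xi - rep(cent[l, ], each = nrow(xi)))^2)
  }
  s <- sqrt(ss / (n - K))
  s0 <- stats::median(s)
  mk <- sqrt(1 / as.numeric(nk) - 1 / n)
  d <- (cent - rep(xbar, each = K)) / (mk %o% (s + s0))
  d_shr <- sign(d) * pmax(abs(d) - threshold, 0)
  cent_shr <- rep(xbar, each = K) + (mk %o% (s + s0)) * d_shr
  structure(list(levels = levels(y), prior = as.numeric(nk) / n,
                 centroids = cent_shr, d_shrunk = d_shr,
                 s = s, s0 = s0, threshold = threshold,
                 features = colnames(x)),
            class = "nsc_model")
}

#' Predict positive-class scores from a nearest shrunken centroids model
#' @param model an \code{nsc_model}.
#' @param x numeric matrix with the training columns.
#' @return positive-class posterior scores in [0, 1].
#' @export
nsc_predict <- function(model, x) {
  x <- as.matrix(x)[, model$features, drop = FALSE]
  disc <- vapply(seq_along(model$levels), function(k) {
    rowSums((x - rep(model$centroids[k, ], each = nrow(x)))^2 /
              rep((model$s + model$s0)^2, each = nrow(x))) -
      2 * log(model$prior[k])
  }, numeric(nrow(x)))
  if (is.null(dim(disc))) disc <- matrix(disc, nrow = nrow(x))
  # posterior ~ exp(-disc/2), normalized in log space
  lw <- -disc / 2
  lw <- lw - apply(lw, 1, max)
  w <- exp(lw)
  (w / rowSums(w))[, length(model$levels)]
}

#' Feature importance of an NSC model
#'
#' The absolute shrunken standardized difference of each surviving feature
#' (zero for fully shrunk features).
#' @param model an \code{nsc_model}.
#' @return named numeric vector, decreasing.
#' @export
nsc_importance <- function(model) {
  imp <- apply(abs(model$d_shrunk), 2, max)
  names(imp) <- model$features
  sort(imp, decreasing = TRUE)
}

# ---- k-nearest neighbours (native) ----------------------------------------

#' Fit/predict a k-nearest-neighbour classifier
#'
#' Predictors are standardized with the training means/SDs; the score is the
#' positive-class vote fraction among the k nearest training subjects
#' (Euclidean distance, deterministic tie-break by training order).
#'
#' @param x training matrix.
#' @param y two-level factor; second level = positive.
#' @param k number of neighbours (<= training size).
#' @return object of class \code{knn_model}.
#' @export
knn_fit <- function(x, y, k) {
  x <- as.matrix(x)
  if (k > nrow(x)) stop("knn_fit: k exceeds training size")
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1
  structure(list(x = sweep(sweep(x, 2, ctr), 2, scl, "/"),
                 y = droplevels(as.factor(y)), k = k,
                 center = ctr, scale = scl),
            class = "knn_model")
}

#' @rdname knn_fit
#' @param model a \code{knn_model}.
#' @export
knn_predict <- function(model, x) {
  x <- sweep(sweep(as.matrix(x), 2, model$center), 2, model$scale, "/")
  pos <- model$y == levels(model$y)[2]
  apply(x, 1, function(r) {
    d2 <- rowSums((model$x - rep(r, each = nrow(model$x)))^2)
    nb <- order(d2)[seq_len(model$k)]
    mean(pos[nb])
  })
}

# ---- naive Bayes (native, Gaussian or kernel) -----------------------------

#' Fit/predict a naive Bayes classifier
#'
#' Per-class, per-feature conditional densities are either Gaussian
#' (mean/SD) or a nonparametric Gaussian-kernel density estimate; class
#' posteriors accumulate log-likelihoods plus log priors.
#'
#' @param x training matrix.
#' @param y two-level factor; second level = positive.
#' @param kernel use a kernel density estimate instead of a Gaussian fit.
#' @param bandwidth kernel bandwidth; \code{NULL} = Silverman's rule per
#'   class/feature.
#' @return object of class \code{gnb_model}.
#' @export
gnb_fit <- function(x, y, kernel = FALSE, bandwidth = NULL) {
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  cls <- levels(y)
  pars <- lapply(cls, function(l) {
    xi <- x[y == l, , drop = FALSE]
    list(mean = colMeans(xi),
         sd = pmax(apply(xi, 2, stats::sd), 1e-9),
         values = xi)
  })
  names(pars) <- cls
  structure(list(levels = cls, prior = as.numeric(table(y)) / length(y),
                 pars = pars, kernel = kernel, bandwidth = bandwidth,
                 features = colnames(x)),
            class = "gnb_model")
}

#' @rdname gnb_fit
#' @param model a \code{gnb_model}.
#' @export
gnb_predict <- function(model, x) {
  x <- as.matrix(x)[, model$features, drop = FALSE]
  loglik <- vapply(seq_along(model$levels), function(k) {
    p <- model$pars[[k]]
    ll <- numeric(nrow(x))
    for (j in seq_len(ncol(x))) {
      if (model$kernel) {
        h <- model$bandwidth
        if (is.null(h)) h <- max(stats::bw.nrd0(p$values[, j]), 1e-9)
        tr <- p$values[, j]
        dens <- vapply(x[, j], function(v) {
          mean(stats::dnorm((v - tr) / h)) / h
        }, numeric(1))
        ll <- ll + log(pmax(dens, 1e-300))
      } else {
        ll <- ll + stats::dnorm(x[, j], p$mean[j], p$sd[j], log = TRUE)
      }
    }
    ll + log(model$prior[k])
  }, numeric(nrow(x)))
  if (is.null(dim(loglik))) loglik <- matrix(loglik, nrow = nrow(x))
  lw <- loglik - apply(loglik, 1, max)
  w <- exp(lw)
  (w / rowSums(w))[, length(model$levels)]
}

# ---- bundled classifiers for the harness ----------------------------------

#' Native reference classifiers
#'
#' Classifier objects satisfying the \code{\link{make_classifier}} contract.
#' \code{classifier_nsc} tunes its shrinkage threshold over a grid (default
#' 30 values from 0.325 to 9.097) by inner stratified resampling of the
#' training split; \code{classifier_knn} tunes k over 5 to 15 the same way;
#' \code{classifier_gnb} has no tuning parameter.
#'
#' @param threshold_grid NSC shrinkage grid.
#' @param k_grid kNN neighbour grid.
#' @param inner_splits inner resampling splits used for tuning (default 5).
#' @param kernel naive Bayes: kernel density instead of Gaussian.
#' @return a \code{csf_classifier}.
#' @name native_classifiers
NULL

#' @rdname native_classifiers
#' @export
classifier_nsc <- function(threshold_grid = seq(0.325, 9.097,
                                                length.out = 30),
                           inner_splits = 5) {
  make_classifier(
    "nsc",
    fit = function(x, y) {
      thr <- tune_grid(threshold_grid, x, y, inner_splits,
                       function(g, xt, yt) nsc_fit(xt, yt, g),
                       nsc_predict)
      nsc_fit(x, y, thr)
    },
    predict = nsc_predict,
    importance = nsc_importance
  )
}

#' @rdname native_classifiers
#' @export
classifier_knn <- function(k_grid = 5:15, inner_splits = 5) {
  make_classifier(
    "knn",
    fit = function(x, y) {
      kg <- k_grid[k_grid <= nrow(x) - 2]
      k <- tune_grid(kg, x, y, inner_splits,
                     function(g, xt, yt) knn_fit(xt, yt, g),
                     knn_predict)
      knn_fit(x, y, k)
    },
    predict = knn_predict
  )
}

#' @rdname native_classifiers
#' @export
classifier_gnb <- function(kernel = FALSE) {
  make_classifier(
    if (kernel) "nb_kernel" else "nb_gaussian",
    fit = function(x, y) gnb_fit(x, y, kernel = kernel),
    predict = gnb_predict
  )
}

# Inner-resampling grid tuning on the training split only: picks the grid
# value with the best mean held-out AUC over stratified inner splits.
tune_grid <- function(grid, x, y, inner_splits, fit_fun, predict_fun) {
  if (length(grid) <= 1) return(grid[1])
  y <- droplevels(as.factor(y))
  perf <- numeric(length(grid))
  splits <- lapply(seq_len(inner_splits), function(s) {
    stratified_split(y, 0.8)
  })
  for (gi in seq_along(grid)) {
    aucs <- vapply(splits, function(sp) {
      m <- tryCatch(fit_fun(grid[gi], x[sp$train, , drop = FALSE],
                            y[sp$train]),
                    error = function(e) NULL)
      if (is.null(m)) return(NA_real_)
      sc <- predict_fun(m, x[sp$test, , drop = FALSE])
      tryCatch(empirical_auc(sc, y[sp$test])$auc, error = function(e) NA_real_)
    }, numeric(1))
    perf[gi] <- mean(aucs, na.rm = TRUE)
  }
  grid[which.max(perf)]
}

# Stratified train/test split preserving the class ratio within +/- 1.
stratified_split <- function(y, train_frac) {
  train <- integer(0)
  for (l in levels(y)) {
    idx <- which(y == l)
    n_tr <- max(1L, min(length(idx) - 1L, round(train_frac * length(idx))))
    train <- c(train, sample(idx, n_tr))
  }
  list(train = sort(train), test = setdiff(seq_along(y), train))
}

#' Predictor matrix for the harness
#'
#' Marker columns from the (transformed) cohort plus the demographics that
#' enter every model: age at lumbar puncture, gender (female = 1) and APOE
#' epsilon-4 carrier status.
#' @param cohort a \code{cohort_table}.
#' @param markers analyte names.
#' @return numeric matrix.
#' @export
build_predictors <- function(cohort, markers) {
  X <- cohort$analytes[, markers, drop = FALSE]
  cbind(X,
        age = cohort$subjects$age_at_lp,
        female = as.numeric(cohort$subjects$gender == "female"),
        apoe4 = as.numeric(cohort$subjects$e4_carrier))
}

#' Repeated stratified train/test evaluation of a classifier
#'
#' The data are repeatedly split into stratified training (default 80\%) and
#' test (20\%) sets; the classifier is fitted on each training split (any
#' tuning happens inside its \code{fit} on that split only) and scored on the
#' held-out subjects. Sensitivity and specificity are taken at the
#' argmax-posterior operating point (score >= 0.5), the AUC from the held-out
#' scores, and all metrics are averaged over splits. Splits on which the
#' classifier fails are excluded and counted.
#'
#' @param classifier a \code{csf_classifier}.
#' @param x numeric predictor matrix (use \code{\link{build_predictors}} to
#'   append the always-included demographics).
#' @param y two-level factor labels; second level = positive class.
#' @param n_splits number of random splits (default 200).
#' @param train_frac training fraction (default 0.80).
#' @param seed integer seed.
#' @return object of class \code{resampling_result} with the per-split
#'   records and means.
#' @export
resample_evaluate <- function(classifier, x, y, n_splits = 200,
                              train_frac = 0.80, seed = 1L) {
  stopifnot(inherits(classifier, "csf_classifier"))
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  keep <- stats::complete.cases(x)
  x <- x[keep, , drop = FALSE]; y <- y[keep]
  set.seed(as.integer(seed))
  rec <- vector("list", n_splits)
  failed <- 0L
  for (s in seq_len(n_splits)) {
    sp <- stratified_split(y, train_frac)
    row <- tryCatch({
      m <- classifier$fit(x[sp$train, , drop = FALSE], y[sp$train])
      sc <- classifier$predict(m, x[sp$test, , drop = FALSE])
      yt <- y[sp$test] == levels(y)[2]
      pred_pos <- sc >= 0.5
      sens <- mean(pred_pos[yt])
      spec <- mean(!pred_pos[!yt])
      data.frame(split = s, sensitivity = sens, specificity = spec,
                 youden = youden_index(sens, spec),
                 auc = empirical_auc(sc, y[sp$test])$auc)
    }, error = function(e) NULL)
    if (is.null(row)) failed <- failed + 1L else rec[[s]] <- row
  }
  per_split <- do.call(rbind, rec)
  if (is.null(per_split) || nrow(per_split) == 0) {
    stop("resample_evaluate: classifier failed on every split")
  }
  means <- colMeans(per_split[c("sensitivity", "specificity", "youden",
                                "auc")])
  structure(list(model = classifier$name, n_splits = n_splits,
                 n_failed = failed, per_split = per_split,
                 sensitivity = means[["sensitivity"]],
                 specificity = means[["specificity"]],
                 youden = means[["youden"]], auc = means[["auc"]]),
            class = "resampling_result")
}

#' @export
print.resampling_result <- function(x, ...) {
  cat(sprintf("%s over %d splits (%d failed):\n", x$model, x$n_splits,
              x$n_failed))
  cat(sprintf("  sensitivity %.3f  specificity %.3f  Youden %.3f  AUC %.3f\n",
              x$sensitivity, x$specificity, x$youden, x$auc))
  invisible(x)
}

#' Overlap of top-k importance rankings
#'
#' Pairwise and global intersection counts of the top-k predictor sets of
#' several models, optionally intersected with an external reference set
#' (e.g. the markers selected by the targeted ROC analysis).
#'
#' @param rankings named list of ordered character vectors (most important
#'   first).
#' @param k top-set size (default 15).
#' @param reference_set optional character vector.
#' @return list: \code{top_sets}, \code{pairwise} (count matrix),
#'   \code{global} (size of the common intersection),
#'   \code{reference_overlap} (per model, if a reference was given).
#' @export
importance_overlap <- function(rankings, k = 15, reference_set = NULL) {
  if (length(rankings) < 2) stop("importance_overlap: need >= 2 rankings")
  short <- vapply(rankings, length, integer(1)) < k
  if (any(short)) {
    stop("importance_overlap: ranking(s) shorter than k: ",
         paste(names(rankings)[short], collapse = ", "))
  }
  tops <- lapply(rankings, function(r) r[seq_len(k)])
  nm <- names(tops)
  pw <- matrix(NA_integer_, length(tops), length(tops),
               dimnames = list(nm, nm))
  for (i in seq_along(tops)) {
    for (j in seq_along(tops)) {
      pw[i, j] <- length(intersect(tops[[i]], tops[[j]]))
    }
  }
  glob <- length(Reduce(intersect, tops))
  out <- list(top_sets = tops, pairwise = pw, global = glob)
  if (!is.null(reference_set)) {
    out$reference_overlap <- vapply(tops, function(t) {
      length(intersect(t, reference_set))
    }, integer(1))
  }
  out
}
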