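#' Empirical AUC (Mann-Whitney estimator)
#'
#' Probability that a randomly chosen case scores above a randomly chosen
#' control, with ties counted 1/2. The raw orientation (cases = positive
#' class = second factor level or \code{TRUE}/1) is returned together with an
#' oriented variant folded above 0.5; orientation is never forced silently.
#'
#' @param scores numeric vector.
#' @param labels logical, 0/1 or two-level factor; the second level (or
#'   \code{TRUE}) is the case group.
#' @return list: \code{auc} (raw orientation), \code{auc_oriented}
#'   (\code{max(auc, 1 - auc)}).
#' @export
empirical_auc <- function(scores, labels) {
  y <- as_case_indicator(labels)
  ok <- !is.na(scores) & !is.na(y)
  y <- y[ok]; s <- scores[ok]
  n1 <- as.numeric(sum(y)); n0 <- as.numeric(sum(!y))
  if (n1 == 0 || n0 == 0) stop("empirical_auc: both classes must be present")
  r <- rank(s)                       # midranks handle ties as 1/2
  auc <- (sum(r[y]) - n1 * (n1 + 1) / 2) / (n0 * n1)
  list(auc = auc, auc_oriented = max(auc, 1 - auc))
}

as_case_indicator <- function(labels) {
  if (is.factor(labels)) {
    if (nlevels(labels) != 2) stop("labels must have exactly 2 levels")
    labels == levels(labels)[2]
  } else if (is.logical(labels)) {
    labels
  } else {
    as.numeric(labels) > 0
  }
}

new_binormal_model <- function(markers, mu0, mu1, sigma0, sigma1,
                               ridge = 0) {
  sigma0 <- as.matrix(sigma0); sigma1 <- as.matrix(sigma1)
  m <- structure(list(markers = markers,
                      mu0 = stats::setNames(as.numeric(mu0), markers),
                      mu1 = stats::setNames(as.numeric(mu1), markers),
                      sigma0 = sigma0, sigma1 = sigma1, ridge = ridge),
                 class = "binormal_model")
  oc <- optimal_combination(m)
  m$a <- oc$a
  m$auc <- oc$auc
  m
}

#' Fit a binormal model to a marker panel
#'
#' Per-group sample means and unbiased sample covariances of the panel
#' columns, assuming (approximate) multivariate normality within each group
#' -- markers should already be on their analysis (possibly log10) scale. The
#' optimal linear combination and its analytic AUC are attached.
#'
#' @param x numeric matrix or data.frame of marker values (columns = panel).
#' @param labels case/control labels (see \code{\link{empirical_auc}}).
#' @param strict if TRUE, a singular summed covariance is an error; otherwise
#'   a small logged ridge is added.
#' @return object of class \code{binormal_model} with fields \code{markers},
#'   \code{mu0}, \code{mu1}, \code{sigma0}, \code{sigma1}, \code{a}
#'   (unit-length combination coefficients), \code{auc}.
#' @export
fit_binormal <- function(x, labels, strict = FALSE) {
  x <- as.matrix(x)
  y <- as_case_indicator(labels)
  ok <- stats::complete.cases(x) & !is.na(y)
  x <- x[ok, , drop = FALSE]; y <- y[ok]
  n0 <- sum(!y); n1 <- sum(y)
  if (n0 < ncol(x) + 1 || n1 < ncol(x) + 1) {
    stop("fit_binormal: need per-group n > panel size")
  }
  mu0 <- colMeans(x[!y, , drop = FALSE])
  mu1 <- colMeans(x[y, , drop = FALSE])
  s0 <- stats::cov(x[!y, , drop = FALSE])
  s1 <- stats::cov(x[y, , drop = FALSE])
  S <- s0 + s1
  ridge <- 0
  if (rcond_safe(S) < 1e-12) {
    if (strict) stop("fit_binormal: singular pooled covariance")
    ridge <- 1e-8 * mean(diag(S))
    message("fit_binormal: ridge ", format(ridge), " added to singular fit")
  }
  mk <- colnames(x)
  if (is.null(mk)) mk <- paste0("m", seq_len(ncol(x)))
  new_binormal_model(mk, mu0, mu1, s0, s1, ridge = ridge)
}

rcond_safe <- function(S) {
  if (length(S) == 1) return(ifelse(S[1] > 0, 1, 0))
  tryCatch(rcond(S), error = function(e) 0)
}

#' Optimal linear combination of a binormal panel
#'
#' The combination maximizing the AUC under binormality: coefficients
#' proportional to \code{solve(sigma0 + sigma1, mu1 - mu0)} (Su-Liu), scaled
#' to unit length with the sign that points from controls to cases, and the
#' analytic AUC \code{pnorm(sqrt(t(delta) \%*\% solve(sigma0 + sigma1) \%*\%
#' delta))}. For a single marker this reduces to
#' \code{pnorm(|delta| / sqrt(var0 + var1))}.
#'
#' @param model a \code{binormal_model}.
#' @return list: \code{a} (unit-length coefficients), \code{auc}.
#' @export
optimal_combination <- function(model) {
  d <- model$mu1 - model$mu0
  S <- model$sigma0 + model$sigma1
  if (model$ridge > 0) S <- S + diag(model$ridge, nrow(S))
  a_raw <- tryCatch(solve(S, d), error = function(e) {
    stop("optimal_combination: singular summed covariance; ",
         "refit with the ridge option")
  })
  q <- sum(d * a_raw)                      # delta' (S0+S1)^-1 delta >= 0
  auc <- stats::pnorm(sqrt(max(q, 0)))
  nrm <- sqrt(sum(a_raw^2))
  a <- if (nrm > 0) a_raw / nrm else {
    a0 <- numeric(length(d)); a0[1] <- 1; a0
  }
  list(a = stats::setNames(as.numeric(a), model$markers), auc = auc)
}

#' Binormal AUC of an arbitrary combination direction
#'
#' \code{pnorm(a' delta / sqrt(a' (sigma0 + sigma1) a))}; useful for checking
#' that the closed-form optimum dominates random directions.
#' @param model a \code{binormal_model}.
#' @param a coefficient vector (any scale).
#' @return AUC in [0, 1] (raw orientation of \code{a}).
#' @export
combination_auc <- function(model, a) {
  d <- model$mu1 - model$mu0
  S <- model$sigma0 + model$sigma1
  stats::pnorm(sum(a * d) / sqrt(sum(a * (S %*% a))))
}

#' Sensitivity at a fixed specificity
#'
#' For a \code{binormal_model}, the closed form: the threshold is set on the
#' combination score of the control group, \code{c = a'mu0 +
#' qnorm(spec) * sqrt(a'sigma0 a)}, and sensitivity is
#' \code{pnorm((a'mu1 - c) / sqrt(a'sigma1 a))}. For empirical scores, the
#' threshold is the control-score quantile at the target specificity and
#' sensitivity is the fraction of cases above it.
#'
#' @param x a \code{binormal_model}, or a numeric score vector.
#' @param specificity target specificity in (0, 1), default 0.80.
#' @param labels required for the empirical (numeric) method.
#' @param ... unused.
#' @return sensitivity in [0, 1].
#' @export
sensitivity_at_specificity <- function(x, specificity = 0.80, ...) {
  UseMethod("sensitivity_at_specificity")
}

#' @rdname sensitivity_at_specificity
#' @export
sensitivity_at_specificity.binormal_model <- function(x, specificity = 0.80,
                                                      ...) {
  check_spec(specificity)
  a <- x$a
  s0 <- sqrt(sum(a * (x$sigma0 %*% a)))
  s1 <- sqrt(sum(a * (x$sigma1 %*% a)))
  cthr <- sum(a * x$mu0) + stats::qnorm(specificity) * s0
  stats::pnorm((sum(a * x$mu1) - cthr) / s1)
}

#' @rdname sensitivity_at_specificity
#' @export
sensitivity_at_specificity.default <- function(x, specificity = 0.80,
                                               labels = NULL, ...) {
  check_spec(specificity)
  if (is.null(labels)) stop("labels required for empirical sensitivity")
  y <- as_case_indicator(labels)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (!any(y) || all(y)) stop("both classes must be present")
  cthr <- stats::quantile(x[!y], probs = specificity, names = FALSE, type = 7)
  mean(x[y] > cthr)
}

check_spec <- function(s) {
  if (!is.numeric(s) || s <= 0 || s >= 1) {
    stop("specificity must lie in (0, 1)")
  }
}

#' Combination scores of a fitted panel
#'
#' @param model a \code{binormal_model}.
#' @param x matrix/data.frame holding the model's marker columns.
#' @return numeric vector \code{x[, markers] \%*\% a}.
#' @export
panel_scores <- function(model, x) {
  as.numeric(as.matrix(x)[, model$markers, drop = FALSE] %*% model$a)
}

#' Expand ranked 2-marker panels into 3-marker panels
#'
#' Combines the \code{n_base} best 2-marker panels with the
#' \code{n_candidates} best single markers. A candidate already inside a base
#' panel is skipped, duplicate marker sets arising by different routes are
#' removed, and the ordering is deterministic by (base rank, candidate rank).
#'
#' @param ranked_2marker_panels list of character vectors, best first.
#' @param ranked_single_markers character vector, best first.
#' @param n_base number of base panels used (default 4).
#' @param n_candidates number of candidate markers used (default 10).
#' @return list of 3-marker character vectors.
#' @export
expand_panels <- function(ranked_2marker_panels, ranked_single_markers,
                          n_base = 4, n_candidates = 10) {
  if (length(ranked_2marker_panels) < n_base) {
    warning("expand_panels: only ", length(ranked_2marker_panels),
            " base panels available")
    n_base <- length(ranked_2marker_panels)
  }
  if (length(ranked_single_markers) < n_candidates) {
    warning("expand_panels: only ", length(ranked_single_markers),
            " candidate markers available")
    n_candidates <- length(ranked_single_markers)
  }
  bases <- ranked_2marker_panels[seq_len(n_base)]
  cands <- ranked_single_markers[seq_len(n_candidates)]
  out <- list()
  seen <- character(0)
  for (b in bases) {
    for (cc in cands) {
      if (cc %in% b) next
      panel <- c(b, cc)
      key <- paste(sort(panel), collapse = "\r")
      if (key %in% seen) next
      seen <- c(seen, key)
      out[[length(out) + 1]] <- panel
    }
  }
  out
}

#' Bootstrap evaluation of a panel against its nested reduced panel
#'
#' For each of \code{B} stratified bootstrap resamples (drawn with
#' replacement within the case and control groups, preserving the original
#' group sizes), binormal models are fitted for the full and the reduced
#' panel; the analytic AUC and sensitivity at the target specificity of the
#' full panel are recorded, together with a one-sided p-value for
#' AUC(full) > AUC(reduced) from the paired DeLong comparison of the two
#' panels' combination scores on the resample. Means, SDs and 95\%
#' normal-theory confidence intervals (mean +/- 1.96 SD / sqrt(B)) over the B
#' iterations are reported.
#'
#' @param x matrix/data.frame of transformed marker values.
#' @param labels case/control labels.
#' @param panel character vector of marker names (must contain
#'   \code{reduced_panel}).
#' @param reduced_panel nested comparison panel.
#' @param B bootstrap iterations (default 100, >= 2).
#' @param specificity sensitivity reporting target (default 0.80).
#' @param seed integer seed.
#' @param max_redraws degenerate resamples (a group too small or collapsed to
#'   singularity) are redrawn up to this many times in total, with a count
#'   reported.
#' @return object of class \code{panel_evaluation}.
#' @export
bootstrap_evaluate <- function(x, labels, panel, reduced_panel, B = 100,
                               specificity = 0.80, seed = 1L,
                               max_redraws = 100) {
  if (B < 2) stop("bootstrap_evaluate: B must be >= 2")
  if (!all(reduced_panel %in% panel)) {
    stop("bootstrap_evaluate: reduced_panel must be nested in panel")
  }
  x <- as.matrix(x)[, panel, drop = FALSE]
  y <- as_case_indicator(labels)
  ok <- stats::complete.cases(x) & !is.na(y)
  x <- x[ok, , drop = FALSE]; y <- y[ok]
  i0 <- which(!y); i1 <- which(y)
  same <- setequal(reduced_panel, panel)
  set.seed(as.integer(seed))
  auc <- sens <- pval <- numeric(B)
  redraws <- 0L
  b <- 1L
  while (b <= B) {
    idx <- c(sample(i0, length(i0), replace = TRUE),
             sample(i1, length(i1), replace = TRUE))
    res <- tryCatch({
      xb <- x[idx, , drop = FALSE]
      yb <- y[idx]
      mf <- fit_binormal(xb, yb)
      auc_b <- mf$auc
      sens_b <- sensitivity_at_specificity(mf, specificity)
      p_b <- if (same) 1 else {
        mr <- fit_binormal(xb[, reduced_panel, drop = FALSE], yb)
        delong_paired_p(panel_scores(mf, xb), panel_scores(mr, xb), yb)
      }
      list(auc = auc_b, sens = sens_b, p = p_b)
    }, error = function(e) NULL)
    if (is.null(res)) {
      redraws <- redraws + 1L
      if (redraws > max_redraws) {
        stop("bootstrap_evaluate: too many degenerate resamples")
      }
      next
    }
    auc[b] <- res$auc; sens[b] <- res$sens; pval[b] <- res$p
    b <- b + 1L
  }
  summ <- function(v) {
    m <- mean(v); s <- stats::sd(v)
    c(mean = m, sd = s, ci_lo = m - 1.96 * s / sqrt(B),
      ci_hi = m + 1.96 * s / sqrt(B))
  }
  structure(list(panel = panel, reduced_panel = reduced_panel, B = B,
                 specificity = specificity,
                 auc = summ(auc), sensitivity = summ(sens), p_value = summ(pval),
                 redraws = redraws,
                 iterations = data.frame(auc = auc, sensitivity = sens,
                                         p_value = pval)),
            class = "panel_evaluation")
}

#' @export
print.panel_evaluation <- function(x, ...) {
  cat("panel:", paste(x$panel, collapse = " + "), "\n")
  cat(sprintf("  AUC %.4f (SD %.4f, 95%% CI %.4f-%.4f)\n",
              x$auc["mean"], x$auc["sd"], x$auc["ci_lo"], x$auc["ci_hi"]))
  cat(sprintf("  sensitivity at %.0f%% specificity %.4f (SD %.4f)\n",
              100 * x$specificity, x$sensitivity["mean"],
              x$sensitivity["sd"]))
  cat(sprintf("  p vs {%s}: %.4f\n",
              paste(x$reduced_panel, collapse = " + "),
              x$p_value["mean"]))
  invisible(x)
}

#' One-sided paired DeLong p-value for AUC(s1) > AUC(s2)
#'
#' Placement-value (DeLong) normal approximation to the paired difference of
#' two correlated empirical AUCs computed on the same subjects.
#' @param s1,s2 score vectors on the same subjects.
#' @param labels case/control labels.
#' @return p-value for the alternative AUC(s1) > AUC(s2); defined as 1 when
#'   the scores are identical.
#' @export
delong_paired_p <- function(s1, s2, labels) {
  y <- as_case_indicator(labels)
  n1 <- sum(y); n0 <- sum(!y)
  placements <- function(s) {
    cases <- s[y]; ctrls <- s[!y]
    v10 <- vapply(cases, function(c_i) {
      (sum(c_i > ctrls) + 0.5 * sum(c_i == ctrls)) / n0
    }, numeric(1))
    v01 <- vapply(ctrls, function(c_j) {
      (sum(cases > c_j) + 0.5 * sum(cases == c_j)) / n1
    }, numeric(1))
    list(v10 = v10, v01 = v01, auc = mean(v10))
  }
  p1 <- placements(s1); p2 <- placements(s2)
  dauc <- p1$auc - p2$auc
  if (isTRUE(all.equal(s1, s2))) return(1)
  v10 <- stats::var(p1$v10 - p2$v10)
  v01 <- stats::var(p1$v01 - p2$v01)
  se <- sqrt(v10 / n1 + v01 / n0)
  if (!is.finite(se) || se == 0) return(if (dauc > 0) 0 else 1)
  stats::pnorm(dauc / se, lower.tail = FALSE)
}

#' Add a derived ratio marker to a cohort
#'
#' Ratios of established markers (e.g. tau / amyloid-beta 42) are computed on
#' the raw concentration scale before any transformation and flagged for
#' log10 transformation downstream. Apply after below-LDL imputation so the
#' denominator is never 0.
#'
#' @param cohort a \code{cohort_table}.
#' @param numerator,denominator analyte names.
#' @param name name of the new marker (default
#'   \code{"<numerator>_over_<denominator>"}).
#' @return the cohort with the ratio appended.
#' @export
add_ratio_marker <- function(cohort, numerator, denominator,
                             name = paste0(numerator, "_over_", denominator)) {
  num <- cohort$analytes[, numerator]
  den <- cohort$analytes[, denominator]
  if (any(den == 0, na.rm = TRUE)) {
    stop("add_ratio_marker: zero denominator; impute below-LDL cells first")
  }
  r <- num / den
  cohort$analytes <- cbind(cohort$analytes, r)
  colnames(cohort$analytes)[ncol(cohort$analytes)] <- name
  extra <- cohort$analyte_meta[1, , drop = FALSE]
  extra$analyte <- name
  extra$unit <- "ratio"
  extra$ldl <- min(r[r > 0], na.rm = TRUE) / 10
  if (!is.null(extra$lognormal)) extra$lognormal <- TRUE
  if (!is.null(extra$transform)) extra$transform <- "log10"
  cohort$analyte_meta <- rbind(cohort$analyte_meta, extra)
  rownames(cohort$analyte_meta) <- NULL
  cohort
}
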