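#' Measurability filter
#'
#' Flags each analyte as retained when at most \code{threshold} of its values
#' are missing or below the lower detection limit; analytes strictly above
#' the threshold are excluded from analysis. Missing and below-LDL cells are
#' pooled for this rule.
#'
#' @param cohort a \code{cohort_table}.
#' @param threshold maximum tolerated missing-or-below-LDL fraction
#'   (default 0.10; an analyte at exactly the threshold is retained).
#' @return data.frame of class \code{qc_report} with one row per analyte:
#'   \code{analyte}, \code{missing_frac}, \code{below_ldl_frac},
#'   \code{affected_frac}, \code{retained}.
#' @export
flag_measurable <- function(cohort, threshold = 0.10) {
  n <- nrow(cohort$analytes)
  miss <- colMeans(is.na(cohort$analytes))
  bl <- colMeans(below_ldl_mask(cohort))
  affected <- miss + bl
  rep <- data.frame(analyte = colnames(cohort$analytes),
                    missing_frac = miss, below_ldl_frac = bl,
                    affected_frac = affected,
                    retained = !(affected > threshold),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(rep) <- c("qc_report", "data.frame")
  rep
}

#' Impute below-detection-limit values to LDL/2
#'
#' @param values numeric vector of concentrations (censored readings encoded
#'   as values below the LDL, typically 0; \code{NA} = truly missing, left
#'   untouched).
#' @param ldl the analyte's lower detection limit (> 0).
#' @return the vector with every below-LDL cell set to \code{ldl / 2}.
#' @export
impute_below_ldl <- function(values, ldl) {
  if (!is.finite(ldl) || ldl <= 0) stop("ldl must be > 0")
  b <- !is.na(values) & values < ldl
  values[b] <- ldl / 2
  values
}

#' Nearest-neighbour imputation of extreme outliers
#'
#' Detects cells more than \code{z_cutoff} standard deviations from the
#' analyte mean and replaces them with the mean of the analyte in the
#' \code{k} nearest subjects. Detection uses a one-pass trimmed mean/SD: a
#' provisional mean/SD over all observed values flags provisional outliers,
#' the mean/SD are recomputed without them, and a single final sweep with the
#' trimmed moments fixes the outlier set (no iteration, so the result is
#' deterministic). Nearness is Euclidean distance over all other retained
#' analytes, each standardized, averaged over co-observed dimensions;
#' neighbours must hold a non-outlying observed value of the target analyte.
#'
#' Below-LDL imputation is expected to have run first; outlier detection and
#' imputation operate on the raw (untransformed) scale.
#'
#' @param cohort a \code{cohort_table} whose below-LDL cells are already
#'   imputed.
#' @param z_cutoff SD multiple defining an outlier (default 5).
#' @param k neighbours averaged for the replacement value (default 5).
#' @param retained optional character vector of analyte names to process
#'   (defaults to all).
#' @return list with \code{cohort} (imputed) and \code{outliers}, a
#'   data.frame listing subject, analyte, original and imputed value.
#' @export
impute_outliers_nn <- function(cohort, z_cutoff = 5, k = 5, retained = NULL) {
  X <- cohort$analytes
  if (is.null(retained)) retained <- colnames(X)
  jset <- match(retained, colnames(X))
  trimmed <- function(v) {
    m1 <- mean(v, na.rm = TRUE); s1 <- stats::sd(v, na.rm = TRUE)
    if (!is.finite(s1) || s1 == 0) return(c(m1, s1))
    keep <- is.na(v) | abs(v - m1) <= z_cutoff * s1
    c(mean(v[keep], na.rm = TRUE), stats::sd(v[keep], na.rm = TRUE))
  }
  mom <- vapply(jset, function(j) trimmed(X[, j]), numeric(2))
  out_mask <- matrix(FALSE, nrow(X), ncol(X))
  for (i in seq_along(jset)) {
    j <- jset[i]
    s <- mom[2, i]
    if (!is.finite(s) || s == 0) next
    out_mask[, j] <- !is.na(X[, j]) & abs(X[, j] - mom[1, i]) > z_cutoff * s
  }
  rec <- NULL
  if (any(out_mask)) {
    # standardized matrix (outliers masked) used for the distance metric
    Z <- X[, jset, drop = FALSE]
    Z[out_mask[, jset, drop = FALSE]] <- NA
    Z <- sweep(sweep(Z, 2, mom[1, ], "-"), 2, mom[2, ], "/")
    cells <- which(out_mask, arr.ind = TRUE)
    vals <- numeric(nrow(cells))
    for (r in seq_len(nrow(cells))) {
      i <- cells[r, 1]; j <- cells[r, 2]
      jz <- match(j, jset)
      donor_ok <- !is.na(X[, j]) & !out_mask[, j]
      donor_ok[i] <- FALSE
      if (!any(donor_ok)) {
        stop("imputation error: no donor subjects for analyte ",
             colnames(X)[j])
      }
      d2 <- rowMeans((Z[, -jz, drop = FALSE] -
                        rep(Z[i, -jz], each = nrow(Z)))^2, na.rm = TRUE)
      d2[!donor_ok] <- Inf
      nb <- order(d2)[seq_len(min(k, sum(donor_ok)))]
      vals[r] <- mean(X[nb, j])
    }
    rec <- data.frame(subject_id = cohort$subjects$subject_id[cells[, 1]],
                      analyte = colnames(X)[cells[, 2]],
                      original = X[cells], imputed = vals,
                      stringsAsFactors = FALSE)
    X[cells] <- vals
  } else {
    rec <- data.frame(subject_id = character(0), analyte = character(0),
                      original = numeric(0), imputed = numeric(0))
  }
  cohort$analytes <- X
  list(cohort = cohort, outliers = rec)
}

#' Box-Cox driven transform selection
#'
#' Estimates the maximum-likelihood Box-Cox exponent with a profile-likelihood
#' 95\% confidence interval and chooses a log10 transform when the interval
#' excludes 1 and the point estimate is near zero (|lambda| < 0.5), i.e. when
#' the data look closer to log-normal than normal; otherwise the identity is
#' kept. Any non-positive value forces the identity (logging is undefined).
#'
#' @param values numeric vector (at least 20 positive observations for a
#'   Box-Cox fit).
#' @return list of class \code{transform_spec}: \code{transform}
#'   (\code{"log10"} or \code{"identity"}), \code{lambda}, \code{lambda_ci},
#'   \code{rationale}.
#' @export
select_transform <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) == 0 || stats::sd(v) == 0) {
    stop("select_transform: constant or empty vector")
  }
  spec <- function(tr, lam, ci, why) {
    structure(list(transform = tr, lambda = lam, lambda_ci = ci,
                   rationale = why), class = "transform_spec")
  }
  if (any(v <= 0)) {
    return(spec("identity", NA_real_, c(NA_real_, NA_real_), "nonpositive_values"))
  }
  if (length(v) < 20) {
    return(spec("identity", NA_real_, c(NA_real_, NA_real_), "too_few_observations"))
  }
  grid <- seq(-2, 2, by = 0.01)
  bc <- MASS::boxcox(v ~ 1, lambda = grid, plotit = FALSE)
  ll <- bc$y
  lam_hat <- bc$x[which.max(ll)]
  keep <- ll >= max(ll) - stats::qchisq(0.95, 1) / 2
  ci <- range(bc$x[keep])
  if ((ci[1] > 1 || ci[2] < 1) && abs(lam_hat) < 0.5) {
    spec("log10", lam_hat, ci, "ci_excludes_1_lambda_near_0")
  } else {
    spec("identity", lam_hat, ci, "compatible_with_identity")
  }
}

#' Full QC pass over a cohort
#'
#' Fixed, logged order: measurability filter, LDL/2 imputation of below-LDL
#' cells in retained analytes, nearest-neighbour outlier imputation (raw
#' scale), then per-analyte Box-Cox transform selection. Missing cells remain
#' missing (downstream analyses delete casewise). The pass is idempotent:
#' running it on its own output changes nothing.
#'
#' @param cohort a \code{cohort_table}.
#' @param config a \code{\link{run_config}}.
#' @return list of class \code{qc_result}: \code{cohort} (cleaned, retained
#'   analytes only), \code{measurability} (per-analyte \code{qc_report}),
#'   \code{outliers} (imputed-cell log), \code{transforms} (named list of
#'   \code{transform_spec}).
#' @export
qc_pipeline <- function(cohort, config = run_config()) {
  meas <- flag_measurable(cohort, config$missing_threshold)
  keep <- meas$analyte[meas$retained]
  if (length(keep) == 0) {
    stop("empty-input error: no analyte passes the measurability filter")
  }
  cohort$analytes <- cohort$analytes[, keep, drop = FALSE]
  cohort$analyte_meta <- cohort$analyte_meta[
    match(keep, cohort$analyte_meta$analyte), , drop = FALSE]
  for (j in seq_along(keep)) {
    cohort$analytes[, j] <- impute_below_ldl(cohort$analytes[, j],
                                             cohort$analyte_meta$ldl[j])
  }
  imp <- impute_outliers_nn(cohort, z_cutoff = config$outlier_z,
                            k = config$nn_k)
  cohort <- imp$cohort
  transforms <- lapply(seq_along(keep), function(j) {
    select_transform(cohort$analytes[, j])
  })
  names(transforms) <- keep
  structure(list(cohort = cohort, measurability = meas,
                 outliers = imp$outliers, transforms = transforms),
            class = "qc_result")
}

#' Apply selected transforms to the analyte matrix
#'
#' @param cohort a cleaned \code{cohort_table}.
#' @param transforms named list of \code{transform_spec} (or a character
#'   vector of \code{"log10"}/\code{"identity"}).
#' @return the cohort with log10-flagged analytes transformed; the metadata
#'   gains a \code{transform} column.
#' @export
apply_transforms <- function(cohort, transforms) {
  tr <- if (is.character(transforms)) {
    transforms
  } else {
    vapply(transforms, function(s) s$transform, character(1))
  }
  tr <- tr[colnames(cohort$analytes)]
  for (j in seq_along(tr)) {
    if (identical(unname(tr[j]), "log10")) {
      cohort$analytes[, j] <- log10(cohort$analytes[, j])
    }
  }
  cohort$analyte_meta$transform <- unname(tr)
  cohort
}
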