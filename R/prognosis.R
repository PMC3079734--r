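#' Standard Z-score
#'
#' Centered by the sample mean, scaled by the sample SD so that hazard ratios
#' of different markers are comparable per SD.
#' @param values numeric vector (missing allowed; a constant vector is an
#'   error).
#' @return standardized vector, mean 0 and SD 1 over the non-missing values.
#' @export
zscore <- function(values) {
  m <- mean(values, na.rm = TRUE)
  s <- stats::sd(values, na.rm = TRUE)
  if (!is.finite(s) || s == 0) stop("zscore: constant vector")
  (values - m) / s
}

#' Reciprocal marker
#'
#' Computes 1/value before any log or Z-scoring, so that a marker whose
#' *decrease* raises risk (e.g. amyloid-beta 42) carries a hazard ratio above
#' 1 in Cox models.
#' @param values positive numeric vector.
#' @return 1 / values.
#' @export
reciprocal_marker <- function(values) {
  if (any(values == 0, na.rm = TRUE)) {
    stop("reciprocal_marker: zero value")
  }
  1 / values
}

#' Fit a Cox proportional-hazards model
#'
#' Maximizes the Cox partial likelihood (Newton-Raphson, Efron handling of
#' the heavily tied annual-visit conversion times) and reports per-covariate
#' hazard ratios with Wald 95\% confidence intervals and p-values, the
#' partial log-likelihood, \code{AIC = -2 logPL + 2 k}, and the overall
#' hazard ratio (product of the component hazard ratios, i.e.
#' \code{exp(sum(beta))}).
#'
#' @param records a \code{followup_records} data.frame (\code{time_to_event},
#'   \code{event}).
#' @param covariates data.frame of numeric covariates aligned with
#'   \code{records} rows; markers should be Z-scored, age left in raw years.
#' @return object of class \code{cox_model_result}.
#' @export
cox_fit <- function(records, covariates) {
  covariates <- as.data.frame(covariates)
  stopifnot(nrow(covariates) == nrow(records))
  if (sum(records$event) < 1) stop("cox_fit: need at least one event")
  d <- cbind(data.frame(.time = records$time_to_event,
                        .event = records$event), covariates)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", names(covariates)), collapse = " + ")))
  fit <- survival::coxph(fml, data = d, ties = "efron",
                         control = survival::coxph.control(iter.max = 50))
  if (any(!is.finite(stats::coef(fit)))) {
    stop("cox_fit: no convergence in 50 iterations")
  }
  sm <- summary(fit)
  beta <- stats::coef(fit)
  k <- length(beta)
  res <- data.frame(covariate = names(covariates),
                    beta = as.numeric(beta),
                    hr = as.numeric(exp(beta)),
                    hr_lo = sm$conf.int[, "lower .95"],
                    hr_hi = sm$conf.int[, "upper .95"],
                    p = sm$coefficients[, "Pr(>|z|)"],
                    row.names = NULL, stringsAsFactors = FALSE)
  logpl <- fit$loglik[2]
  structure(list(covariates = res, log_partial_lik = logpl,
                 aic = -2 * logpl + 2 * k,
                 overall_hr = round(prod(res$hr), 3),
                 n = fit$n, n_events = fit$nevent, fit = fit),
            class = "cox_model_result")
}

#' @export
print.cox_model_result <- function(x, ...) {
  cat(sprintf("Cox model: %d subjects, %d events, AIC %.1f, overall HR %.3f\n",
              x$n, x$n_events, x$aic, x$overall_hr))
  print(x$covariates, digits = 4)
  invisible(x)
}

#' Overall hazard ratio of a model
#'
#' The product of the component hazard ratios (equivalently the exponential
#' of the coefficient sum), reported to 3 decimals.
#' @param model a \code{cox_model_result}, or a numeric vector of hazard
#'   ratios.
#' @return single numeric value.
#' @export
overall_hr <- function(model) {
  hrs <- if (inherits(model, "cox_model_result")) {
    model$covariates$hr
  } else {
    as.numeric(model)
  }
  round(prod(hrs), 3)
}

#' Staged selection of a prognostic marker panel
#'
#' Implements the staged Cox selection protocol on the baseline CDR 0
#' analysis set:
#' \enumerate{
#'   \item Univariate Cox model per candidate marker (Z-scored over the
#'     analysis set); markers with p < \code{screen_alpha} (default 0.15) are
#'     considered further.
#'   \item Any pair of surviving markers with Spearman |rho| >=
#'     \code{corr_threshold} (default 0.4) and correlation p < 0.05 is never
#'     co-included: the conflict graph is split into alternative candidate
#'     sets (maximal independent sets), each evaluated separately.
#'   \item Each candidate set is fitted jointly with age (raw years), gender
#'     and APOE epsilon-4 status; covariates with p >= \code{retention_alpha}
#'     (default 0.05) are dropped backward one at a time (largest p first),
#'     re-testing age and gender at every step.
#'   \item Final models are ranked by AIC (lower is better); the minimum-AIC
#'     model is flagged and the overall hazard ratio attached to each.
#' }
#'
#' @param cohort a cleaned, transformed \code{cohort_table} (markers on their
#'   analysis scale).
#' @param records \code{followup_records} for the CDR 0 subjects.
#' @param candidate_markers analyte names to screen.
#' @param screen_alpha univariate inclusion threshold (default 0.15).
#' @param retention_alpha multivariate retention threshold (default 0.05).
#' @param corr_threshold |Spearman rho| above which two markers are split
#'   into alternative models (default 0.4).
#' @return list of class \code{panel_selection}: \code{models} (list of
#'   \code{cox_model_result}, AIC-ranked), \code{best} (index 1 model),
#'   \code{trace} (univariate screen, conflict arbitration records, candidate
#'   sets).
#' @export
select_prognostic_panel <- function(cohort, records, candidate_markers,
                                    screen_alpha = 0.15,
                                    retention_alpha = 0.05,
                                    corr_threshold = 0.4) {
  if (nrow(records) == 0) stop("select_prognostic_panel: no records")
  ids <- match(records$subject_id, cohort$subjects$subject_id)
  if (anyNA(ids)) stop("records reference unknown subjects")
  X <- cohort$analytes[ids, candidate_markers, drop = FALSE]
  Xz <- apply(X, 2, function(v) {
    v[is.na(v)] <- mean(v, na.rm = TRUE)   # sporadic missingness only
    zscore(v)
  })
  demo <- data.frame(
    age = cohort$subjects$age_at_lp[ids],
    female = as.numeric(cohort$subjects$gender[ids] == "female"),
    apoe4 = as.numeric(cohort$subjects$e4_carrier[ids]))

  # stage 1: univariate screen
  uni <- do.call(rbind, lapply(candidate_markers, function(m) {
    f <- cox_fit(records, stats::setNames(data.frame(Xz[, m]), m))
    data.frame(marker = m, hr = f$covariates$hr, p = f$covariates$p,
               stringsAsFactors = FALSE)
  }))
  kept <- uni$marker[uni$p < screen_alpha]

  if (length(kept) == 0) {
    base <- backward_cox(records, demo, retention_alpha)
    return(structure(list(
      models = list(base), best = base,
      note = "no marker passed the univariate screen; covariate-only model",
      trace = list(univariate = uni, conflicts = NULL,
                   candidate_sets = list(character(0)))),
      class = "panel_selection"))
  }

  # stage 2: correlated-pair arbitration
  conflicts <- NULL
  adj <- matrix(FALSE, length(kept), length(kept),
                dimnames = list(kept, kept))
  if (length(kept) > 1) {
    for (i in seq_along(kept)) {
      for (j in seq_len(i - 1)) {
        s <- spearman_rho(Xz[, kept[i]], Xz[, kept[j]])
        if (!is.na(s$rho) && abs(s$rho) >= corr_threshold && s$p < 0.05) {
          adj[i, j] <- adj[j, i] <- TRUE
          conflicts <- rbind(conflicts, data.frame(
            marker_a = kept[i], marker_b = kept[j], rho = s$rho,
            rho_p = s$p, stringsAsFactors = FALSE))
        }
      }
    }
  }
  sets <- maximal_independent_sets(adj)

  # stage 3: backward elimination per candidate set (age/gender/APOE always
  # entered, re-tested at every step)
  models <- list()
  keys <- character(0)
  for (set in sets) {
    cov <- cbind(as.data.frame(Xz[, set, drop = FALSE]), demo)
    m <- backward_cox(records, cov, retention_alpha)
    key <- paste(sort(m$covariates$covariate), collapse = "|")
    if (!key %in% keys) {
      keys <- c(keys, key)
      models[[length(models) + 1]] <- m
    }
  }

  # stage 4: AIC ranking
  ord <- order(vapply(models, function(m) m$aic, numeric(1)))
  models <- models[ord]
  structure(list(models = models, best = models[[1]],
                 trace = list(univariate = uni, conflicts = conflicts,
                              candidate_sets = sets)),
            class = "panel_selection")
}

# All maximal independent sets of a small conflict graph (exhaustive
# enumeration; the surviving candidate panel is small so this is cheap).
maximal_independent_sets <- function(adj) {
  nm <- rownames(adj)
  n <- length(nm)
  if (n == 0) return(list(character(0)))
  if (!any(adj)) return(list(nm))
  if (n > 16) {
    stop("conflict graph too large for exhaustive arbitration (",
         n, " markers); raise corr_threshold or prefilter candidates")
  }
  subsets <- lapply(seq_len(2^n) - 1, function(mask) {
    which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
  })
  indep <- Filter(function(s) {
    length(s) < 2 || !any(adj[s, s, drop = FALSE])
  }, subsets)
  is_maximal <- vapply(indep, function(s) {
    others <- setdiff(seq_len(n), s)
    all(vapply(others, function(v) {
      length(s) > 0 && any(adj[v, s])
    }, logical(1)))
  }, logical(1))
  lapply(indep[is_maximal], function(s) nm[s])
}

# Backward elimination: drop the worst covariate with p >= alpha, refit,
# until all survive; if everything is eliminated, return the null model.
backward_cox <- function(records, covariates, alpha) {
  cov <- covariates
  repeat {
    fit <- cox_fit(records, cov)
    worst <- which.max(fit$covariates$p)
    if (fit$covariates$p[worst] < alpha) {
      return(fit)
    }
    if (ncol(cov) == 1) {
      logpl0 <- fit$fit$loglik[1]
      return(structure(list(
        covariates = fit$covariates[0, , drop = FALSE],
        log_partial_lik = logpl0, aic = -2 * logpl0,
        overall_hr = 1, n = fit$n, n_events = fit$n_events, fit = NULL),
        class = "cox_model_result"))
    }
    cov <- cov[, -worst, drop = FALSE]
  }
}
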