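#' Run the full discovery-and-prognosis pipeline on a synthetic cohort
#'
#' Chains every stage end to end: cohort simulation, QC (measurability
#' filter, LDL/2 and outlier imputation, transform selection), the
#' covariate-adjusted univariate screen, binormal ROC panel construction with
#' bootstrap evaluation, the repeated-split classifier harness, conversion
#' simulation and staged Cox panel selection. All randomness derives from
#' \code{seed}, so two runs with equal arguments produce byte-identical
#' report tables.
#'
#' @param scenario a \code{\link{sim_scenario}}; the traditional markers are
#'   required (set \code{traditional = TRUE}) because panels are built around
#'   the tau / amyloid-beta-42 ratio.
#' @param config a \code{\link{run_config}}; \code{bootstrap_B} and
#'   \code{n_splits} control the expensive stages.
#' @param seed integer master seed (stage seeds are derived from it).
#' @param n_panels how many expanded 3-marker panels to bootstrap-evaluate
#'   (default 4; the full expansion is returned unevaluated).
#' @param out_dir optional directory: report CSVs and a JSON manifest are
#'   written via \code{\link{write_report}}.
#' @return list with the stage results (\code{qc}, \code{screen},
#'   \code{panels}, \code{ml}, \code{prognosis}) and \code{tables}, the
#'   data.frames written to the report.
#' @export
run_pipeline <- function(scenario = sim_scenario(traditional = TRUE),
                         config = run_config(), seed = config$seed,
                         n_panels = 4, out_dir = NULL) {
  seed <- as.integer(seed)
  gen <- generate_cohort(scenario, seed)
  cohort <- gen$cohort

  qc <- qc_pipeline(cohort, config)
  clean <- qc$cohort
  if (!all(c("tau", "abeta42") %in% colnames(clean$analytes))) {
    stop("run_pipeline: scenario must include the traditional markers")
  }
  clean <- add_ratio_marker(clean, "tau", "abeta42")
  qc$transforms[["tau_over_abeta42"]] <- structure(
    list(transform = "log10", lambda = NA_real_,
         lambda_ci = c(NA_real_, NA_real_), rationale = "derived_ratio"),
    class = "transform_spec")
  trans <- apply_transforms(clean, qc$transforms)

  screen <- ancova_screen(trans, n_tests = config$bonferroni_n)

  # ROC panels: rank analytes by single-marker binormal AUC, pair the best
  # established marker (the tau/amyloid ratio) with the top analytes, expand
  # to 3-marker panels, bootstrap-evaluate the leading ones
  grp <- cdr_group(trans)
  rbm <- setdiff(colnames(trans$analytes),
                 c("tau", "abeta42", "ptau181", "tau_over_abeta42"))
  single_auc <- vapply(rbm, function(m) {
    fit_binormal(trans$analytes[, m, drop = FALSE], grp)$auc
  }, numeric(1))
  ranked_singles <- names(sort(single_auc, decreasing = TRUE))
  pair_auc <- vapply(ranked_singles[1:min(10, length(ranked_singles))],
                     function(m) {
    fit_binormal(trans$analytes[, c("tau_over_abeta42", m)], grp)$auc
  }, numeric(1))
  ranked_pairs <- lapply(names(sort(pair_auc, decreasing = TRUE)),
                         function(m) c("tau_over_abeta42", m))
  panels3 <- expand_panels(ranked_pairs, ranked_singles,
                           n_base = min(4, length(ranked_pairs)),
                           n_candidates = min(10, length(ranked_singles)))
  evals <- lapply(panels3[seq_len(min(n_panels, length(panels3)))],
                  function(p) {
    bootstrap_evaluate(trans$analytes, grp, p, p[1:2],
                       B = config$bootstrap_B,
                       specificity = config$specificity_target,
                       seed = seed + 1L)
  })
  panel_table <- do.call(rbind, lapply(evals, function(e) {
    data.frame(panel = paste(e$panel, collapse = " + "),
               auc = e$auc[["mean"]], auc_sd = e$auc[["sd"]],
               auc_lo = e$auc[["ci_lo"]], auc_hi = e$auc[["ci_hi"]],
               sensitivity = e$sensitivity[["mean"]],
               sensitivity_sd = e$sensitivity[["sd"]],
               p_vs_reduced = e$p_value[["mean"]],
               stringsAsFactors = FALSE)
  }))

  # ML harness: traditional-only vs traditional + panel analytes
  trad <- intersect(c("tau", "abeta42", "ptau181"), colnames(trans$analytes))
  labels <- grp
  ml_rows <- list()
  for (pred_set in c("traditional", "traditional_rbm")) {
    markers <- if (pred_set == "traditional") trad else c(trad, rbm)
    x <- build_predictors(trans, markers)
    for (clf in list(classifier_nsc(inner_splits = 3),
                     classifier_gnb())) {
      r <- resample_evaluate(clf, x, labels, n_splits = config$n_splits,
                             train_frac = config$train_frac,
                             seed = seed + 2L)
      ml_rows[[length(ml_rows) + 1]] <- data.frame(
        model = r$model, predictors = pred_set,
        sensitivity = r$sensitivity, specificity = r$specificity,
        youden = r$youden, auc = r$auc, stringsAsFactors = FALSE)
    }
  }
  ml_table <- do.call(rbind, ml_rows)

  # prognosis: simulate conversions driven by the strongest screened analyte
  # and low amyloid, then recover a panel with the staged selector
  top_marker <- screen$analyte[screen$analyte %in% rbm][1]
  surv <- generate_survival(
    cohort, stats::setNames(c(log(1.75), log(2.45), log(1.10)),
                            c(top_marker, "abeta42", "age")) *
      c(1, -1, 1),                       # low amyloid raises risk
    baseline_hazard = 0.03, followup_years = 10, seed = seed + 3L)
  prog_cohort <- trans
  prog_cohort$analytes <- cbind(
    prog_cohort$analytes,
    recip_abeta42 = -prog_cohort$analytes[, "abeta42"])  # log10 1/x = -log10 x
  cand <- unique(c(utils::head(screen$analyte[screen$analyte %in% rbm], 5),
                   "tau", "recip_abeta42"))
  sel <- select_prognostic_panel(prog_cohort, surv$records, cand,
                                 screen_alpha = config$screen_alpha,
                                 retention_alpha = config$retention_alpha,
                                 corr_threshold = config$cox_corr_threshold)
  cox_table <- do.call(rbind, lapply(seq_along(sel$models), function(i) {
    m <- sel$models[[i]]
    if (nrow(m$covariates) == 0) return(NULL)
    data.frame(model = i, covariate = m$covariates$covariate,
               hr = m$covariates$hr, hr_lo = m$covariates$hr_lo,
               hr_hi = m$covariates$hr_hi, p = m$covariates$p,
               aic = m$aic, overall_hr = m$overall_hr,
               stringsAsFactors = FALSE)
  }))

  tables <- list(screen = as.data.frame(screen), panels = panel_table,
                 ml = ml_table, cox = cox_table)
  if (!is.null(out_dir)) {
    write_report(tables, out_dir, config)
  }
  list(qc = qc, screen = screen, panel_evaluations = evals,
       ml = ml_table, prognosis = sel, tables = tables)
}
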