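#' Construct a cohort table
#'
#' The universal input container for all pipeline stages: one row per subject
#' with demographics and Clinical Dementia Rating (CDR), plus a numeric matrix
#' of analyte concentrations and a sidecar of per-analyte metadata (unit and
#' lower detection limit, LDL).
#'
#' Below-LDL (censored) measurements are encoded as \code{0} in the analyte
#' matrix: a multiplex immunoassay never reports a concentration strictly
#' between 0 and the LDL, so any stored value in \code{(0, LDL)} is treated as
#' below the detection limit by downstream QC. Truly missing cells are
#' \code{NA}.
#'
#' @param subjects data.frame with columns \code{subject_id}, \code{age_at_lp}
#'   (years), \code{gender} (\code{"female"}/\code{"male"}), \code{apoe}
#'   (genotype string such as \code{"e3e4"}), \code{cdr} (0, 0.5 or 1).
#' @param analytes numeric matrix, one row per subject, one column per
#'   analyte; column names are analyte names.
#' @param analyte_meta data.frame with columns \code{analyte}, \code{unit},
#'   \code{ldl} (lower detection limit, must be > 0).
#' @return An object of class \code{cohort_table}.
#' @export
cohort_table <- function(subjects, analytes, analyte_meta) {
  stopifnot(is.data.frame(subjects), is.data.frame(analyte_meta))
  analytes <- as.matrix(analytes)
  storage.mode(analytes) <- "double"
  req <- c("subject_id", "age_at_lp", "gender", "apoe", "cdr")
  miss <- setdiff(req, names(subjects))
  if (length(miss) > 0) {
    stop("schema error: missing required subject column(s): ",
         paste(miss, collapse = ", "))
  }
  subjects$subject_id <- as.character(subjects$subject_id)
  if (anyDuplicated(subjects$subject_id)) {
    stop("integrity error: duplicate subject_id: ",
         paste(unique(subjects$subject_id[duplicated(subjects$subject_id)]),
               collapse = ", "))
  }
  if (!all(subjects$cdr %in% c(0, 0.5, 1))) {
    stop("integrity error: cdr values must be in {0, 0.5, 1}")
  }
  if (!all(subjects$gender %in% c("female", "male"))) {
    stop("integrity error: gender must be 'female' or 'male'")
  }
  if (nrow(analytes) != nrow(subjects)) {
    stop("integrity error: analyte matrix rows (", nrow(analytes),
         ") do not match subject count (", nrow(subjects), ")")
  }
  mreq <- c("analyte", "unit", "ldl")
  if (!all(mreq %in% names(analyte_meta))) {
    stop("schema error: analyte_meta needs columns ",
         paste(mreq, collapse = ", "))
  }
  if (is.null(colnames(analytes))) {
    stop("integrity error: analyte matrix must have column names")
  }
  if (!identical(colnames(analytes), as.character(analyte_meta$analyte))) {
    extra <- setdiff(colnames(analytes), analyte_meta$analyte)
    if (length(extra) > 0) {
      stop("integrity error: analytes missing from LDL/metadata table: ",
           paste(extra, collapse = ", "))
    }
    analyte_meta <- analyte_meta[match(colnames(analytes),
                                       analyte_meta$analyte), , drop = FALSE]
    rownames(analyte_meta) <- NULL
  }
  if (any(!is.finite(analyte_meta$ldl)) || any(analyte_meta$ldl <= 0)) {
    stop("integrity error: every LDL must be a finite value > 0")
  }
  subjects$e4_carrier <- apoe_e4_carrier(subjects$apoe)
  rownames(analytes) <- subjects$subject_id
  structure(list(subjects = subjects, analytes = analytes,
                 analyte_meta = analyte_meta),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("cohort_table:", nrow(x$subjects), "subjects x",
      ncol(x$analytes), "analytes\n")
  cat("  CDR groups:",
      paste(sprintf("%s=%d", names(table(x$subjects$cdr)),
                    as.integer(table(x$subjects$cdr))), collapse = ", "), "\n")
  cat("  missing cells:", sum(is.na(x$analytes)),
      " below-LDL cells:", sum(below_ldl_mask(x)), "\n")
  invisible(x)
}

#' APOE epsilon-4 carrier status from a genotype string
#'
#' Any e4 allele (e.g. "e3e4", "e4e4") counts as carrier.
#' @param apoe character vector of genotype strings.
#' @return logical vector.
#' @export
apoe_e4_carrier <- function(apoe) {
  grepl("4", as.character(apoe), fixed = TRUE)
}

#' Indicator matrix of below-detection-limit cells
#'
#' A cell is below-LDL when its stored value is non-missing and strictly less
#' than the analyte's LDL (the encoding uses 0 for censored readings).
#' @param cohort a \code{cohort_table}.
#' @return logical matrix, same shape as \code{cohort$analytes}.
#' @export
below_ldl_mask <- function(cohort) {
  ldl <- matrix(cohort$analyte_meta$ldl, nrow = nrow(cohort$analytes),
                ncol = ncol(cohort$analytes), byrow = TRUE)
  m <- !is.na(cohort$analytes) & cohort$analytes < ldl
  dimnames(m) <- dimnames(cohort$analytes)
  m
}

#' Binary diagnosis group from CDR
#'
#' The analysis pools very mild (CDR 0.5) and mild (CDR 1) dementia into a
#' single impaired group versus cognitively normal (CDR 0).
#' @param cohort a \code{cohort_table}.
#' @return factor with levels \code{"cdr0"} and \code{"cdr_gt0"}.
#' @export
cdr_group <- function(cohort) {
  factor(ifelse(cohort$subjects$cdr > 0, "cdr_gt0", "cdr0"),
         levels = c("cdr0", "cdr_gt0"))
}

#' Read a cohort from CSV files
#'
#' CSV dialect: comma-separated, UTF-8, "." decimal, empty cell = missing.
#' The wide cohort file must carry \code{subject_id}, \code{age_at_lp},
#' \code{gender}, \code{apoe}, \code{cdr}; every other column is an analyte.
#' The sidecar has one row per analyte with \code{analyte}, \code{unit},
#' \code{ldl}. Unparseable concentration cells become missing and their count
#' is reported via a message.
#'
#' @param path path to the wide cohort CSV.
#' @param ldl_path path to the analyte metadata CSV.
#' @return a \code{cohort_table}.
#' @export
read_cohort <- function(path, ldl_path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE, na.strings = c("", "NA"))
  meta <- utils::read.csv(ldl_path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  req <- c("subject_id", "age_at_lp", "gender", "apoe", "cdr")
  miss <- setdiff(req, names(raw))
  if (length(miss) > 0) {
    stop("schema error: cohort file lacks column(s): ",
         paste(miss, collapse = ", "))
  }
  acols <- setdiff(names(raw), req)
  amat <- matrix(NA_real_, nrow(raw), length(acols),
                 dimnames = list(NULL, acols))
  n_bad <- 0L
  for (j in seq_along(acols)) {
    v <- raw[[acols[j]]]
    if (is.character(v)) {
      num <- suppressWarnings(as.numeric(v))
      n_bad <- n_bad + sum(is.na(num) & !is.na(v))
      amat[, j] <- num
    } else {
      amat[, j] <- as.numeric(v)
    }
  }
  if (n_bad > 0) {
    message("read_cohort: ", n_bad,
            " unparseable concentration cell(s) recorded as missing")
  }
  cohort_table(raw[req], amat, meta)
}

#' Write a cohort to CSV files
#'
#' Inverse of \code{\link{read_cohort}}; round-trips every non-missing value
#' bit-exactly via full-precision decimal formatting.
#' @param cohort a \code{cohort_table}.
#' @param path output path for the wide cohort CSV.
#' @param ldl_path output path for the analyte metadata CSV.
#' @return invisibly, the two paths.
#' @export
write_cohort <- function(cohort, path, ldl_path) {
  s <- cohort$subjects[c("subject_id", "age_at_lp", "gender", "apoe", "cdr")]
  a <- as.data.frame(apply(cohort$analytes, 2, format_full, simplify = FALSE),
                     check.names = FALSE, optional = TRUE)
  utils::write.csv(cbind(s, a), path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  meta <- cohort$analyte_meta
  meta$ldl <- format_full(meta$ldl)
  utils::write.csv(meta, ldl_path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(c(path, ldl_path))
}

# Full-precision decimal text for doubles (17 significant digits round-trips
# IEEE-754 exactly); NA becomes the empty cell.
format_full <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else sprintf("%.17g", v)
  }, character(1))
  out
}

#' Read follow-up (conversion) records
#'
#' One row per baseline CDR 0 subject with at least one follow-up visit:
#' \code{subject_id}, \code{time_to_event} (years from baseline lumbar
#' puncture), \code{event} (1 = converted to CDR > 0, 0 = censored at last
#' assessment).
#' @param path CSV path.
#' @return data.frame of class \code{followup_records}.
#' @export
read_followup <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  followup_records(d)
}

#' Validate follow-up records
#' @param d data.frame with \code{subject_id}, \code{time_to_event},
#'   \code{event}.
#' @return the validated data.frame, classed \code{followup_records}.
#' @export
followup_records <- function(d) {
  req <- c("subject_id", "time_to_event", "event")
  if (!all(req %in% names(d))) {
    stop("schema error: follow-up table needs columns ",
         paste(req, collapse = ", "))
  }
  if (any(d$time_to_event <= 0)) {
    stop("integrity error: time_to_event must be > 0")
  }
  if (!all(d$event %in% c(0, 1))) {
    stop("integrity error: event must be 0 (censored) or 1 (converted)")
  }
  d$subject_id <- as.character(d$subject_id)
  class(d) <- c("followup_records", "data.frame")
  d
}

#' Run configuration
#'
#' Collects the thresholds used across the pipeline together with the run
#' seed, so that a whole analysis is reproducible from one object.
#'
#' @param missing_threshold analyte retained only if its missing-or-below-LDL
#'   fraction is <= this (default 0.10; the rule is strictly-greater-than).
#' @param outlier_z outlier cutoff in SD units (default 5).
#' @param nn_k neighbours for outlier imputation (default 5).
#' @param bootstrap_B bootstrap iterations for panel evaluation (default 100).
#' @param n_splits repeated train/test splits (default 200).
#' @param train_frac training fraction per split (default 0.80).
#' @param specificity_target fixed specificity for panel sensitivity
#'   reporting (default 0.80).
#' @param screen_alpha univariate Cox inclusion threshold (default 0.15).
#' @param retention_alpha multivariate retention threshold (default 0.05).
#' @param bonferroni_n number of tests for the familywise correction
#'   (default 128: measurable multiplex analytes plus the traditional
#'   markers).
#' @param cox_corr_threshold absolute Spearman rho above which two candidate
#'   prognostic markers are never co-included (default 0.4).
#' @param seed integer seed, logged in every manifest.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(missing_threshold = 0.10, outlier_z = 5, nn_k = 5,
                       bootstrap_B = 100, n_splits = 200, train_frac = 0.80,
                       specificity_target = 0.80, screen_alpha = 0.15,
                       retention_alpha = 0.05, bonferroni_n = 128,
                       cox_corr_threshold = 0.4, seed = 1L) {
  fracs <- c(missing_threshold = missing_threshold, train_frac = train_frac,
             specificity_target = specificity_target,
             screen_alpha = screen_alpha, retention_alpha = retention_alpha)
  if (any(fracs <= 0 | fracs >= 1)) {
    stop("parameter error: fractions must lie in (0, 1): ",
         paste(names(fracs)[fracs <= 0 | fracs >= 1], collapse = ", "))
  }
  if (bootstrap_B < 1) stop("parameter error: bootstrap_B must be >= 1")
  cfg <- list(missing_threshold = missing_threshold, outlier_z = outlier_z,
              nn_k = nn_k, bootstrap_B = bootstrap_B, n_splits = n_splits,
              train_frac = train_frac,
              specificity_target = specificity_target,
              screen_alpha = screen_alpha, retention_alpha = retention_alpha,
              bonferroni_n = bonferroni_n,
              cox_corr_threshold = cox_corr_threshold,
              seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

#' Write stage results and a run manifest
#'
#' Writes one CSV per named stage result (layouts mirror the screen, panel,
#' resampling and Cox summary tables a reader of multiplex biomarker studies
#' expects) plus \code{manifest.json} holding the configuration and seed.
#'
#' @param stage_results named list of data.frames (or objects with an
#'   \code{as.data.frame} method). An empty data.frame yields a header-only
#'   CSV.
#' @param path output directory (created if needed).
#' @param config optional \code{run_config} recorded in the manifest.
#' @return invisibly, the vector of files written.
#' @export
write_report <- function(stage_results, path, config = run_config()) {
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(path)) stop("I/O error: cannot create ", path)
  }
  if (is.null(names(stage_results)) || any(names(stage_results) == "")) {
    stop("stage_results must be a fully named list")
  }
  files <- character(0)
  for (nm in names(stage_results)) {
    d <- as.data.frame(stage_results[[nm]])
    num <- vapply(d, is.numeric, logical(1))
    d[num] <- lapply(d[num], format_full)
    f <- file.path(path, paste0(nm, ".csv"))
    utils::write.csv(d, f, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
    files <- c(files, f)
  }
  mf <- file.path(path, "manifest.json")
  jsonlite::write_json(list(config = unclass(config), seed = config$seed,
                            tables = basename(files)),
                       mf, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(files, mf))
}
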