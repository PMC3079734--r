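#' Define a simulation scenario
#'
#' Describes a synthetic multiplex-CSF cohort with the statistical structure
#' the downstream analyses assume: analytes drawn from a two-factor latent
#' Gaussian model (a "tau-like" neurodegeneration factor that many analytes
#' load on, and an "amyloid-like" factor that few load on), group mean shifts
#' on a subset of truly informative analytes, age and gender effects,
#' detection-limit censoring, sporadic missingness and rare extreme outliers.
#'
#' Defaults emulate a 333-subject cohort (242 cognitively normal, 63 very
#' mild, 28 mild dementia) with 125 measurable analytes of which 12 carry a
#' true group shift; per-analyte scales are split between log-normal and
#' normal marginals as is typical of immunoassay panels.
#'
#' @param n_per_group integer vector of length 3: subjects at CDR 0, 0.5, 1.
#' @param n_analytes number of analytes.
#' @param n_signal number of analytes with a true group mean shift.
#' @param effect_sizes standardized latent-scale shifts for the signal
#'   analytes (recycled/truncated to length \code{n_signal}).
#' @param tau_frac,amy_frac fractions of analytes loading on the tau-like and
#'   amyloid-like factors.
#' @param tau_loading_range,amy_loading_range loading ranges (values spread
#'   evenly across the loaded analytes).
#' @param age_effect latent-SD change per year of age for tau-loaded analytes.
#' @param gender_effect latent-SD shift for female subjects on every third
#'   analyte.
#' @param ldl_quantile theoretical lower-tail quantile at which each analyte's
#'   detection limit sits (censoring fraction among CDR 0 subjects).
#' @param missing_rate probability a cell is missing completely at random.
#' @param outlier_rate probability a cell is replaced by an extreme value
#'   5.5--8 SD from the analyte mean.
#' @param lognormal_frac fraction of analytes with log-normal marginals.
#' @param traditional if TRUE, append three established CSF markers
#'   (\code{abeta42}, \code{tau}, \code{ptau181}) with strong factor loadings
#'   and group shifts in the directions seen in dementia (lower amyloid-beta
#'   42, higher tau and phosphorylated tau).
#' @return list of class \code{sim_scenario}.
#' @export
sim_scenario <- function(n_per_group = c(242L, 63L, 28L),
                         n_analytes = 125L,
                         n_signal = min(12L, n_analytes),
                         effect_sizes = seq(1.0, 0.4, length.out = max(n_signal, 1L)),
                         tau_frac = 0.6, amy_frac = 0.1,
                         tau_loading_range = c(0.25, 0.7),
                         amy_loading_range = c(0.2, 0.45),
                         age_effect = 0.03, gender_effect = 0.3,
                         ldl_quantile = 0.02, missing_rate = 0.01,
                         outlier_rate = 0.002, lognormal_frac = 0.5,
                         traditional = FALSE) {
  if (any(n_per_group < 0) || sum(n_per_group) < 2) {
    stop("parameter error: need at least 2 subjects")
  }
  if (n_analytes < 1) stop("parameter error: n_analytes must be >= 1")
  if (n_signal > n_analytes) {
    stop("parameter error: n_signal cannot exceed n_analytes")
  }
  rates <- c(ldl_quantile = ldl_quantile, missing_rate = missing_rate,
             outlier_rate = outlier_rate)
  if (any(rates < 0 | rates >= 1)) {
    stop("parameter error: rates must lie in [0, 1)")
  }
  p <- as.integer(n_analytes)
  analyte <- sprintf("A%03d", seq_len(p))

  # deterministic structure: loadings, effects and marginals are fixed by the
  # scenario; all randomness happens at generation time under the seed
  l_tau <- l_amy <- numeric(p)
  n_tau <- round(tau_frac * p)
  n_amy <- round(amy_frac * p)
  if (n_tau > 0) {
    l_tau[seq_len(n_tau)] <- seq(tau_loading_range[1], tau_loading_range[2],
                                 length.out = n_tau)
  }
  if (n_amy > 0) {
    # amyloid-loaded block sits at the end; it may overlap the tau block
    # when the fractions sum past 1 (dual-loading analytes)
    l_amy[p - n_amy + seq_len(n_amy)] <- seq(amy_loading_range[1],
                                             amy_loading_range[2],
                                             length.out = n_amy)
  }
  if (any(l_tau^2 + l_amy^2 > 1)) {
    stop("parameter error: factor loadings imply a non-PSD covariance")
  }
  shift <- numeric(p)
  if (n_signal > 0) {
    shift[seq_len(n_signal)] <- rep_len(effect_sizes, n_signal)
  }
  age_slope <- ifelse(l_tau > 0, age_effect, 0)
  gender_slope <- ifelse(seq_len(p) %% 3 == 0, gender_effect, 0)
  lognormal <- seq_len(p) %% round(1 / max(lognormal_frac, 1e-9)) == 0
  if (lognormal_frac >= 1) lognormal <- rep(TRUE, p)
  # marginal location/scale: log10-scale for log-normal analytes, raw
  # concentration units otherwise (coefficient of variation ~0.3)
  loc <- ifelse(lognormal, 1 + 2 * (seq_len(p) - 1) / max(p - 1, 1),
                50 + 450 * (seq_len(p) - 1) / max(p - 1, 1))
  scl <- ifelse(lognormal, 0.25, loc * 0.3)

  if (traditional) {
    analyte <- c(analyte, "abeta42", "tau", "ptau181")
    l_tau <- c(l_tau, 0, 0.85, 0.80)
    l_amy <- c(l_amy, 0.85, 0, 0)
    shift <- c(shift, -0.9, 1.1, 1.0)
    age_slope <- c(age_slope, 0, 0.02, 0.02)
    gender_slope <- c(gender_slope, 0, 0, 0)
    lognormal <- c(lognormal, TRUE, TRUE, TRUE)
    loc <- c(loc, 2.74, 2.45, 1.72)
    scl <- c(scl, 0.17, 0.22, 0.20)
    p <- p + 3L
  }

  structure(list(
    n_per_group = as.integer(n_per_group), n_analytes = p,
    analyte = analyte, n_signal = as.integer(n_signal),
    shift = shift, l_tau = l_tau, l_amy = l_amy,
    age_slope = age_slope, gender_slope = gender_slope,
    lognormal = lognormal, loc = loc, scl = scl,
    ldl_quantile = ldl_quantile, missing_rate = missing_rate,
    outlier_rate = outlier_rate,
    age_mean = c(71.6, 74.6, 76.8), age_sd = c(7.4, 7.3, 6.2),
    female_prob = c(0.65, 0.52, 0.50), e4_prob = c(0.32, 0.54, 0.57)
  ), class = "sim_scenario")
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws analytes from the scenario's latent factor model, applies group mean
#' shifts to the signal analytes and age/gender effects, exponentiates
#' log-normal analytes, censors values below each analyte's detection limit
#' (encoded as 0), injects missingness and >5-SD outliers, and returns the
#' cohort together with a truth record from which every derivable quantity
#' (true group means, the factor-implied covariance, true optimal panel
#' combinations and AUCs) can be recomputed in closed form.
#'
#' @param scenario a \code{\link{sim_scenario}}.
#' @param seed integer seed; same scenario + seed gives an identical cohort.
#' @return list with elements \code{cohort} (a \code{cohort_table}) and
#'   \code{truth}.
#' @export
generate_cohort <- function(scenario, seed) {
  stopifnot(inherits(scenario, "sim_scenario"))
  set.seed(as.integer(seed))
  sc <- scenario
  n_g <- sc$n_per_group
  n <- sum(n_g)
  p <- sc$n_analytes
  grp <- rep(c(0, 0.5, 1), times = n_g)

  age <- numeric(n)
  female <- logical(n)
  e4 <- logical(n)
  gi <- rep(1:3, times = n_g)
  for (g in 1:3) {
    idx <- which(gi == g)
    if (length(idx) == 0) next
    a <- stats::rnorm(length(idx), sc$age_mean[g], sc$age_sd[g])
    while (any(a < 60)) {       # enrolment restricted to age >= 60
      k <- a < 60
      a[k] <- stats::rnorm(sum(k), sc$age_mean[g], sc$age_sd[g])
    }
    age[idx] <- round(a, 1)
    female[idx] <- stats::runif(length(idx)) < sc$female_prob[g]
    e4[idx] <- stats::runif(length(idx)) < sc$e4_prob[g]
  }
  apoe <- ifelse(e4,
                 ifelse(stats::runif(n) < 0.85, "e3e4", "e4e4"),
                 ifelse(stats::runif(n) < 0.85, "e3e3", "e2e3"))

  # latent standardized values: factors + unique noise + fixed effects
  f_tau <- stats::rnorm(n)
  f_amy <- stats::rnorm(n)
  uniq <- sqrt(pmax(1 - sc$l_tau^2 - sc$l_amy^2, 0))
  z <- outer(f_tau, sc$l_tau) + outer(f_amy, sc$l_amy) +
    matrix(stats::rnorm(n * p), n, p) * rep(uniq, each = n)
  z <- z + outer(as.numeric(grp > 0), sc$shift)
  z <- z + outer(age - 70, sc$age_slope)
  z <- z + outer(as.numeric(female), sc$gender_slope)

  val <- t(sc$loc + sc$scl * t(z))
  val[, sc$lognormal] <- 10^val[, sc$lognormal]
  colnames(val) <- sc$analyte

  # detection limits: theoretical lower-tail quantile of the CDR 0 marginal
  ldl <- ifelse(sc$lognormal,
                10^(sc$loc + sc$scl * stats::qnorm(pmax(sc$ldl_quantile, 1e-12))),
                pmax(sc$loc + sc$scl * stats::qnorm(pmax(sc$ldl_quantile, 1e-12)),
                     1e-6))
  censored <- sweep(val, 2, ldl, "<")
  val[censored] <- 0

  # extreme outliers: replace with mean +/- U(5.5, 8) SD on the observed scale
  obs <- !censored
  mu_col <- colMeans(ifelse(obs, val, NA), na.rm = TRUE)
  sd_col <- apply(ifelse(obs, val, NA), 2, stats::sd, na.rm = TRUE)
  out_cells <- which(obs & matrix(stats::runif(n * p) < sc$outlier_rate, n, p),
                     arr.ind = TRUE)
  if (nrow(out_cells) > 0) {
    j <- out_cells[, 2]
    mult <- stats::runif(nrow(out_cells), 5.5, 8)
    sgn <- sample(c(-1, 1), nrow(out_cells), replace = TRUE)
    cand <- mu_col[j] + sgn * mult * sd_col[j]
    low <- cand <= ldl[j]                   # keep outliers detectable, not censored
    cand[low] <- mu_col[j[low]] + mult[low] * sd_col[j[low]]
    val[out_cells] <- cand
  }

  miss <- matrix(stats::runif(n * p) < sc$missing_rate, n, p)
  val[miss] <- NA_real_

  subjects <- data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    age_at_lp = age,
    gender = ifelse(female, "female", "male"),
    apoe = apoe, cdr = grp,
    stringsAsFactors = FALSE
  )
  meta <- data.frame(analyte = sc$analyte,
                     unit = ifelse(sc$lognormal, "pg/mL", "ng/mL"),
                     ldl = ldl, lognormal = sc$lognormal,
                     stringsAsFactors = FALSE)
  cohort <- cohort_table(subjects, val, meta)

  truth <- list(
    scenario = sc,
    signal_analytes = sc$analyte[seq_len(sc$n_signal)],
    shift = stats::setNames(sc$shift, sc$analyte),
    analysis_mean_cdr0 = stats::setNames(sc$loc, sc$analyte),
    analysis_mean_cdrgt0 = stats::setNames(sc$loc + sc$scl * sc$shift,
                                           sc$analyte),
    analysis_sd = stats::setNames(sc$scl, sc$analyte),
    outlier_cells = out_cells,
    n_censored = sum(censored), n_missing = sum(miss)
  )
  list(cohort = cohort, truth = truth)
}

#' Factor-model implied correlation matrix of a scenario
#'
#' The latent (analysis-scale) correlation implied by the two-factor model,
#' ignoring age/gender effects: \code{l_tau l_tau' + l_amy l_amy'} off the
#' diagonal, 1 on it.
#' @param scenario a \code{sim_scenario}.
#' @return correlation matrix (analytes x analytes).
#' @export
implied_correlation <- function(scenario) {
  R <- outer(scenario$l_tau, scenario$l_tau) +
    outer(scenario$l_amy, scenario$l_amy)
  diag(R) <- 1
  dimnames(R) <- list(scenario$analyte, scenario$analyte)
  R
}

#' True binormal model of a panel under a scenario
#'
#' Closed-form per-group means and covariance on the analysis scale (log10
#' for log-normal analytes), including the variance contributed by age and
#' gender effects, from which the true optimal linear combination and AUC are
#' computed. Intended for scenarios where the covariate distributions are the
#' same in both groups.
#'
#' @param scenario a \code{sim_scenario}.
#' @param panel character vector of analyte names.
#' @return a \code{binormal_model} (see \code{\link{fit_binormal}}).
#' @export
true_panel_model <- function(scenario, panel) {
  j <- match(panel, scenario$analyte)
  if (anyNA(j)) stop("unknown analyte(s): ",
                     paste(panel[is.na(j)], collapse = ", "))
  sd_age <- mean(scenario$age_sd)
  p_f <- mean(scenario$female_prob)
  L <- cbind(scenario$l_tau[j], scenario$l_amy[j],
             scenario$age_slope[j] * sd_age,
             scenario$gender_slope[j] * sqrt(p_f * (1 - p_f)))
  Rz <- L %*% t(L)
  diag(Rz) <- diag(Rz) + pmax(1 - scenario$l_tau[j]^2 - scenario$l_amy[j]^2, 0)
  S <- diag(scenario$scl[j], nrow = length(j)) %*% Rz %*%
    diag(scenario$scl[j], nrow = length(j))
  mu0 <- scenario$loc[j]
  mu1 <- scenario$loc[j] + scenario$scl[j] * scenario$shift[j]
  new_binormal_model(panel, mu0, mu1, S, S)
}

#' Generate conversion (survival) records for the CDR 0 subjects
#'
#' Latent conversion times follow an exponential proportional-hazards model
#' with linear predictor \code{sum(beta * Z-scored marker) + beta_age *
#' (age - mean age)}; events are observed at the first annual visit after the
#' latent time, and subjects not converting by the last visit are censored
#' there.
#'
#' Marker values enter on the analysis scale (below-LDL cells imputed to
#' LDL/2, missing cells mean-imputed, log10 where the cohort metadata flags a
#' log-normal marginal) and are Z-scored over the CDR 0 analysis set.
#'
#' @param cohort a \code{cohort_table} with CDR 0 subjects.
#' @param true_betas named numeric vector of log-hazard coefficients; names
#'   are analyte names and/or \code{"age"} (per raw year).
#' @param baseline_hazard exponential baseline rate per year (> 0).
#' @param followup_years number of annual visits (last visit = censoring
#'   time).
#' @param seed integer seed.
#' @return list with \code{records} (a \code{followup_records} data.frame)
#'   and \code{truth} (betas and baseline hazard).
#' @export
generate_survival <- function(cohort, true_betas, baseline_hazard,
                              followup_years = 10, seed = 1L) {
  if (baseline_hazard <= 0) {
    stop("parameter error: baseline_hazard must be > 0")
  }
  idx <- which(cohort$subjects$cdr == 0)
  if (length(idx) == 0) stop("cohort has no CDR 0 subjects")
  nm <- names(true_betas)
  markers <- setdiff(nm, "age")
  if (!all(markers %in% colnames(cohort$analytes))) {
    stop("unknown marker(s) in true_betas: ",
         paste(setdiff(markers, colnames(cohort$analytes)), collapse = ", "))
  }
  set.seed(as.integer(seed))
  lp <- numeric(length(idx))
  if (length(markers) > 0) {
    X <- analysis_values(cohort, markers)[idx, , drop = FALSE]
    X <- apply(X, 2, function(v) {
      v[is.na(v)] <- mean(v, na.rm = TRUE)
      zscore(v)
    })
    lp <- lp + as.numeric(X %*% true_betas[markers])
  }
  if ("age" %in% nm) {
    a <- cohort$subjects$age_at_lp[idx]
    lp <- lp + true_betas[["age"]] * (a - mean(a))
  }
  t_latent <- stats::rexp(length(idx), rate = baseline_hazard * exp(lp))
  visit <- ceiling(t_latent)                 # conversions detected annually
  event <- visit <= followup_years
  time <- ifelse(event, visit, followup_years)
  rec <- followup_records(data.frame(
    subject_id = cohort$subjects$subject_id[idx],
    time_to_event = as.numeric(time),
    event = as.integer(event), stringsAsFactors = FALSE))
  list(records = rec,
       truth = list(betas = true_betas, baseline_hazard = baseline_hazard,
                    followup_years = followup_years))
}

# Analysis-scale marker matrix: below-LDL -> LDL/2, log10 where flagged.
analysis_values <- function(cohort, markers = colnames(cohort$analytes)) {
  j <- match(markers, colnames(cohort$analytes))
  X <- cohort$analytes[, j, drop = FALSE]
  ldl <- cohort$analyte_mat_ldl <- cohort$analyte_meta$ldl[j]
  for (k in seq_along(j)) {
    b <- !is.na(X[, k]) & X[, k] < ldl[k]
    X[b, k] <- ldl[k] / 2
  }
  if (!is.null(cohort$analyte_meta$lognormal)) {
    lg <- cohort$analyte_meta$lognormal[j]
    X[, lg] <- log10(X[, lg, drop = FALSE])
  }
  X
}

#' Build a QC fixture with a known number of unmeasurable analytes
#'
#' Returns a cohort in which exactly \code{n_unmeasurable} analytes have more
#' than 10\% of values missing or below the detection limit and all others
#' are at or below 10\%, so the measurability filter's retention count is
#' known by construction.
#'
#' @param n_analytes total analytes (default 190).
#' @param n_unmeasurable analytes forced over the 10\% threshold (default 65).
#' @param seed integer seed.
#' @return a \code{cohort_table} with 333 subjects.
#' @export
make_qc_fixture <- function(n_analytes = 190L, n_unmeasurable = 65L,
                            seed = 1L) {
  if (n_unmeasurable > n_analytes) {
    stop("parameter error: n_unmeasurable cannot exceed n_analytes")
  }
  sc <- sim_scenario(n_analytes = n_analytes, n_signal = 0L,
                     ldl_quantile = 0, missing_rate = 0, outlier_rate = 0)
  gen <- generate_cohort(sc, seed)
  cohort <- gen$cohort
  n <- nrow(cohort$subjects)
  limit <- floor(0.10 * n)                 # affected > limit  <=>  > 10%
  for (j in seq_len(n_analytes)) {
    k <- if (j <= n_unmeasurable) {
      sample((limit + 1):min(n, limit + 70), 1)
    } else {
      sample(0:limit, 1)
    }
    if (k == 0) next
    cells <- sample.int(n, k)
    half <- seq_len(ceiling(k / 2))
    cohort$analytes[cells[half], j] <- NA_real_       # missing
    cohort$analytes[cells[-half], j] <- 0             # below LDL
  }
  cohort
}
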