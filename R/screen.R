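#' Covariate-adjusted group-difference screen (ANCOVA)
#'
#' Fits, per analyte, the linear model \code{value ~ group + age + gender} by
#' least squares (group = CDR 0 vs CDR > 0, pooling very mild and mild
#' dementia) and tests the group effect with a partial F-test. Adjusted
#' (least-squares) means are evaluated at the whole-sample covariate means
#' (gender at its sample proportion) and back-transformed as
#' \code{10^LSmean} for log10 analytes. A secondary model with group x age and
#' group x gender terms supplies interaction p-values; it never alters the
#' main screen.
#'
#' @param cohort a cleaned, transformed \code{cohort_table} (see
#'   \code{\link{apply_transforms}}); missing cells are deleted casewise per
#'   analyte.
#' @param alpha familywise significance level (default 0.05).
#' @param n_tests number of tests for the Bonferroni correction; defaults to
#'   the number of analytes screened.
#' @return data.frame of class \code{screen_result}, one row per analyte:
#'   sample sizes, adjusted and raw means per group, F statistic, p-value,
#'   Bonferroni flag, and interaction p-values.
#' @export
ancova_screen <- function(cohort, alpha = 0.05, n_tests = NULL) {
  grp <- cdr_group(cohort)
  age <- cohort$subjects$age_at_lp
  female <- as.numeric(cohort$subjects$gender == "female")
  tr <- cohort$analyte_meta$transform
  if (is.null(tr)) tr <- rep("identity", ncol(cohort$analytes))
  analytes <- colnames(cohort$analytes)
  if (is.null(n_tests)) n_tests <- length(analytes)
  cutoff <- bonferroni_threshold(alpha, n_tests)$cutoff

  one <- function(j) {
    y <- cohort$analytes[, j]
    ok <- !is.na(y) & !is.na(age) & !is.na(female)
    if (min(table(grp[ok])) < 3) {
      stop("ancova_screen: fewer than 3 subjects per group for ",
           analytes[j])
    }
    d <- data.frame(y = y[ok], group = grp[ok], age = age[ok],
                    female = female[ok])
    mm <- stats::model.matrix(~ group + age + female, d)
    qd <- qr(mm)
    if (qd$rank < ncol(mm)) {
      bad <- colnames(mm)[qd$pivot[(qd$rank + 1):ncol(mm)]]
      stop("rank-deficiency error in design for ", analytes[j],
           ": aliased column(s) ", paste(bad, collapse = ", "))
    }
    fit <- stats::lm(y ~ group + age + female, data = d)
    sm <- summary(fit)$coefficients
    tval <- sm["groupcdr_gt0", "t value"]
    p <- sm["groupcdr_gt0", "Pr(>|t|)"]
    b <- stats::coef(fit)
    abar <- mean(d$age); fbar <- mean(d$female)
    ls0 <- b[1] + b["age"] * abar + b["female"] * fbar
    ls1 <- ls0 + b["groupcdr_gt0"]
    raw <- cohort$analytes[ok, j]
    if (tr[j] == "log10") {
      ls0 <- 10^ls0; ls1 <- 10^ls1
      raw <- 10^raw
    }
    ifit <- stats::lm(y ~ group * age + group * female, data = d)
    ism <- summary(ifit)$coefficients
    gp <- function(nm) if (nm %in% rownames(ism)) ism[nm, "Pr(>|t|)"] else NA_real_
    c(n0 = sum(d$group == "cdr0"), n1 = sum(d$group == "cdr_gt0"),
      adj_mean_cdr0 = unname(ls0), adj_mean_cdrgt0 = unname(ls1),
      raw_mean_cdr0 = mean(raw[d$group == "cdr0"]),
      raw_mean_cdrgt0 = mean(raw[d$group == "cdr_gt0"]),
      F_group = tval^2, p = p,
      p_age_interaction = gp("groupcdr_gt0:age"),
      p_gender_interaction = gp("groupcdr_gt0:female"))
  }
  res <- t(vapply(seq_along(analytes), one, numeric(10)))
  out <- data.frame(analyte = analytes, transform = tr, res,
                    row.names = NULL, stringsAsFactors = FALSE)
  out$bonferroni_significant <- out$p < cutoff
  out <- out[order(out$p), ]
  rownames(out) <- NULL
  class(out) <- c("screen_result", "data.frame")
  out
}

#' Bonferroni per-test cutoff
#'
#' @param alpha familywise level (default 0.05).
#' @param n_tests number of tests (default 128: measurable multiplex analytes
#'   plus the traditional markers).
#' @return list with \code{cutoff} (\code{alpha / n_tests}) and
#'   \code{display} (the cutoff rounded to one significant digit, as usually
#'   printed).
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests = 128) {
  if (n_tests < 1) stop("n_tests must be >= 1")
  cutoff <- alpha / n_tests
  list(cutoff = cutoff, display = signif(cutoff, 1))
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Computes rho on average (midrank) ranks with pairwise deletion of missing
#' values and a two-sided p-value from the t approximation
#' \code{t = rho * sqrt((n - 2) / (1 - rho^2))}.
#'
#' @param x,y numeric vectors of equal length.
#' @param min_pairs minimum complete pairs required (default 10); below this
#'   the correlation is omitted (\code{NA}) and flagged.
#' @return list: \code{rho}, \code{p}, \code{n}, \code{insufficient}.
#' @export
spearman_rho <- function(x, y, min_pairs = 10) {
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < min_pairs) {
    return(list(rho = NA_real_, p = NA_real_, n = n, insufficient = TRUE))
  }
  rx <- rank(x[ok]); ry <- rank(y[ok])
  rho <- stats::cor(rx, ry)
  p <- if (abs(rho) >= 1) {
    0
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(abs(tt), n - 2, lower.tail = FALSE)
  }
  list(rho = rho, p = p, n = n, insufficient = FALSE)
}

#' Correlation table of analytes against reference variables
#'
#' One row per analyte: Spearman rho and p against each reference variable
#' (e.g. age, established CSF markers, amyloid imaging) plus a gender
#' difference p-value from the Mann-Whitney test.
#'
#' @param cohort a cleaned \code{cohort_table}.
#' @param references named list of numeric vectors aligned with the subjects
#'   (e.g. \code{list(age = ..., tau = ...)}).
#' @param min_pairs minimum complete pairs per correlation (default 10).
#' @return data.frame of class \code{correlation_table} with columns
#'   \code{rho_<ref>} / \code{p_<ref>} per reference and \code{gender_p}.
#' @export
spearman_screen <- function(cohort, references, min_pairs = 10) {
  stopifnot(is.list(references), !is.null(names(references)))
  analytes <- colnames(cohort$analytes)
  gender <- cohort$subjects$gender
  rows <- lapply(seq_along(analytes), function(j) {
    v <- cohort$analytes[, j]
    out <- list(analyte = analytes[j])
    for (nm in names(references)) {
      s <- spearman_rho(v, references[[nm]], min_pairs)
      out[[paste0("rho_", nm)]] <- s$rho
      out[[paste0("p_", nm)]] <- s$p
    }
    out$gender_p <- tryCatch(gender_difference(v, gender)$p,
                             error = function(e) NA_real_)
    as.data.frame(out, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  class(res) <- c("correlation_table", "data.frame")
  res
}

#' Mann-Whitney gender-difference test
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test with the tie-corrected
#' normal approximation.
#'
#' @param values numeric vector.
#' @param gender character/factor vector with both levels present.
#' @return list: \code{p}, \code{U} (the rank-sum statistic for the first
#'   group, equal to the count of pairs won plus half the ties).
#' @export
gender_difference <- function(values, gender) {
  ok <- !is.na(values) & !is.na(gender)
  g <- factor(gender[ok])
  if (nlevels(g) != 2 || any(table(g) == 0)) {
    stop("gender_difference: both groups must be non-empty")
  }
  v <- values[ok]
  wt <- stats::wilcox.test(v[g == levels(g)[1]], v[g == levels(g)[2]],
                           exact = FALSE, correct = FALSE)
  list(p = wt$p.value, U = unname(wt$statistic))
}
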