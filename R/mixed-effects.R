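#' Random-intercept linear mixed model with Satterthwaite inference
#'
#' Fits \code{response ~ age * covariate + (1 | subject)} by REML, the
#' second stage of the two-stage growth analysis: the response is the
#' residual series left after removing the selected population growth curve,
#' and the model tests for a covariate main effect and a covariate-by-age
#' interaction while absorbing repeated measurements on the same fetus
#' through a per-subject random intercept. Degrees of freedom and p-values
#' use the Satterthwaite approximation; 95 percent confidence intervals are
#' \code{beta +/- t(df, 0.975) * se}.
#'
#' When no subject contributes more than one observation the random intercept
#' is not identifiable and the fit reduces to ordinary least squares with
#' \code{var_subject = 0} and classical residual degrees of freedom
#' (\code{boundary = TRUE} flags this, as well as REML solutions at the
#' boundary of the variance space).
#'
#' @param data Data frame with the response, covariate, age and subject
#'   columns.
#' @param response,covariate,age,subject Column names. The covariate may be a
#'   factor (sex is coded with female as reference, so male = 1) or numeric
#'   (ordinal confounds such as scan number).
#' @return An \code{lmm_fit}: \code{coefficients} data frame (estimate, se,
#'   df, t, p, ci_lo, ci_hi; rows intercept, age, covariate, age:covariate),
#'   \code{var_subject}, \code{var_resid}, \code{boundary}, \code{n_obs},
#'   \code{n_subjects}.
#' @export
fit_random_intercept_lmm <- function(data, response = "resid",
                                     covariate = "sex", age = "age_days",
                                     subject = "subject") {
  stopifnot(all(c(response, covariate, age, subject) %in% names(data)))
  d <- data.frame(
    y = as.numeric(data[[response]]),
    age = as.numeric(data[[age]]),
    cov = data[[covariate]],
    subject = factor(data[[subject]])
  )
  if (is.character(d$cov)) d$cov <- factor(d$cov)
  if (is.factor(d$cov) && identical(sort(levels(d$cov)), c("F", "M"))) {
    d$cov <- factor(d$cov, levels = c("F", "M"))  # male = 1
  }
  n_levels <- if (is.factor(d$cov)) nlevels(droplevels(d$cov)) else
    length(unique(d$cov))
  if (n_levels < 2L) {
    stop("covariate must vary (>= 2 levels)", call. = FALSE)
  }
  X <- stats::model.matrix(~ age * cov, d)
  if (qr(X)$rank < ncol(X)) {
    stop("fixed-effect design is rank deficient", call. = FALSE)
  }
  if (nlevels(d$subject) < 2L) {
    stop("need at least 2 subjects", call. = FALSE)
  }

  replicated <- any(table(d$subject) > 1L)
  if (!replicated) {
    fit <- stats::lm(y ~ age * cov, data = d)
    sm <- summary(fit)$coefficients
    df <- fit$df.residual
    coefs <- data.frame(
      term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
      df = df, t = sm[, 3], p = sm[, 4], row.names = NULL)
    var_subject <- 0
    var_resid <- summary(fit)$sigma^2
    boundary <- TRUE
  } else {
    fit <- lmerTest::lmer(y ~ age * cov + (1 | subject), data = d, REML = TRUE)
    sm <- stats::coef(summary(fit))  # Satterthwaite df from lmerTest
    coefs <- data.frame(
      term = rownames(sm), estimate = sm[, "Estimate"],
      se = sm[, "Std. Error"], df = sm[, "df"], t = sm[, "t value"],
      p = sm[, "Pr(>|t|)"], row.names = NULL)
    vc <- as.data.frame(lme4::VarCorr(fit))
    var_subject <- vc$vcov[vc$grp == "subject"]
    var_resid <- vc$vcov[vc$grp == "Residual"]
    boundary <- lme4::isSingular(fit, tol = 1e-6)
  }
  tcrit <- stats::qt(0.975, coefs$df)
  coefs$ci_lo <- coefs$estimate - tcrit * coefs$se
  coefs$ci_hi <- coefs$estimate + tcrit * coefs$se
  structure(list(
    coefficients = coefs,
    var_subject = var_subject,
    var_resid = var_resid,
    boundary = boundary,
    n_obs = nrow(d),
    n_subjects = nlevels(d$subject),
    model = fit
  ), class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("Random-intercept LMM (%d obs, %d subjects)\n",
              x$n_obs, x$n_subjects))
  cat(sprintf("var_subject = %.4g, var_resid = %.4g%s\n", x$var_subject,
              x$var_resid, if (x$boundary) " [boundary]" else ""))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Bonferroni adjustment
#'
#' Elementwise \code{min(1, m * p)} for a family of \code{m} comparisons
#' (here: the number of regions tested in the same analysis family).
#'
#' @param p_values Numeric vector of p-values in [0, 1].
#' @param m Family size, >= 1.
#' @return Adjusted p-values.
#' @export
bonferroni_adjust <- function(p_values, m) {
  stopifnot(m >= 1, all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  pmin(1, m * p_values)
}

#' Residual covariate analysis for one region
#'
#' Stage two of the growth analysis: residuals
#' \eqn{r_i = value_i - \hat V(age_i)} are taken from the BIC-selected
#' population growth curve of the region, then modeled with a
#' random-intercept LMM in the covariate (sex or a potential confound) and
#' its interaction with age. Bonferroni correction is applied across the
#' \code{m} regions of the analysis family.
#'
#' @param table Long measurement table with columns \code{subject, sex,
#'   age_days, region, value} (confound columns optional).
#' @param region Region name to analyze.
#' @param selection Optional precomputed \code{growth_selection} for the
#'   pooled population of that region; fitted here when missing.
#' @param covariate Column used as the fixed covariate (default "sex").
#' @param m Bonferroni family size (default 7, the number of volumetric
#'   regions analyzed together).
#' @return A \code{region_effect}: region, selection winner, \code{lmm}
#'   (\code{lmm_fit}), and the coefficient table augmented with
#'   \code{p_bonferroni} and \code{significant} (alpha = 0.05 after
#'   correction).
#' @export
residual_effect_analysis <- function(table, region, selection = NULL,
                                     covariate = "sex", m = 7) {
  rows <- table[table$region == region, , drop = FALSE]
  if (nrow(rows) == 0L) {
    stop("region '", region, "' not present in the table", call. = FALSE)
  }
  if (is.null(selection)) {
    selection <- select_growth_model(rows$age_days, rows$value)
  }
  win <- selection$fits[[selection$winner]]
  rows$resid <- rows$value -
    eval_growth_model(win$family, win$params, rows$age_days)
  lmm <- fit_random_intercept_lmm(rows, response = "resid",
                                  covariate = covariate)
  coefs <- lmm$coefficients
  coefs$p_bonferroni <- bonferroni_adjust(coefs$p, m)
  coefs$significant <- coefs$p_bonferroni < 0.05
  structure(list(
    region = region,
    covariate = covariate,
    winner = selection$winner,
    lmm = lmm,
    coefficients = coefs,
    m = m
  ), class = "region_effect")
}

#' @export
print.region_effect <- function(x, ...) {
  cat(sprintf("Residual %s analysis, region '%s' (growth model: %s, m = %d)\n",
              x$covariate, x$region, x$winner, x$m))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Residual covariate analysis across regions
#'
#' Runs \code{\link{residual_effect_analysis}} for each region with the
#' Bonferroni family size equal to the number of regions tested.
#'
#' @param table Long measurement table.
#' @param regions Regions to test (default: all in the table).
#' @param covariate Fixed covariate column.
#' @return Named list of \code{region_effect} objects, plus an attribute
#'   \code{"summary"} with one coefficient row per region and term.
#' @export
region_effect_table <- function(table, regions = unique(table$region),
                                covariate = "sex") {
  m <- length(regions)
  res <- lapply(regions, function(r) {
    residual_effect_analysis(table, r, covariate = covariate, m = m)
  })
  names(res) <- regions
  summ <- do.call(rbind, lapply(res, function(x) {
    cbind(region = x$region, x$coefficients)
  }))
  rownames(summ) <- NULL
  attr(res, "summary") <- summ
  res
}

#' Screen potential confounding variables
#'
#' One residual LMM per confound column (scanner version, reconstruction
#' method, scan number, acquisition resolution, pulse sequence), mirroring
#' the sex analysis with the confound in place of sex. Confounds with a
#' single observed level are skipped with a warning.
#'
#' @param table Long measurement table carrying the confound columns.
#' @param region Region to analyze.
#' @param selection Optional precomputed \code{growth_selection}.
#' @param confounds Character vector of confound column names.
#' @param m Bonferroni family size passed through.
#' @return Named list of \code{region_effect} objects (skipped confounds
#'   omitted).
#' @export
confound_screen <- function(table, region, selection = NULL,
                            confounds = c("scanner", "recon", "scan_number",
                                          "resolution", "sequence"),
                            m = 7) {
  missing_cols <- setdiff(confounds, names(table))
  if (length(missing_cols)) {
    stop("confound columns absent from table: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- list()
  for (cc in confounds) {
    v <- table[[cc]][table$region == region]
    if (length(unique(v[!is.na(v)])) < 2L) {
      warning("confound '", cc, "' has a single level; skipped",
              call. = FALSE)
      next
    }
    out[[cc]] <- residual_effect_analysis(table, region, selection,
                                          covariate = cc, m = m)
  }
  out
}
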