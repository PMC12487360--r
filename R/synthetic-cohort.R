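#' Mixed-longitudinal cohort design
#'
#' Describes the sampling layout of a simulated fetal cohort: subjects are
#' scanned 1-4 times at target gestational ages, with per-age scan counts
#' matching the atlas design by default, and uniform integer age jitter of
#' up to \code{jitter_days} around each target.
#'
#' @param n_subjects Number of fetuses.
#' @param n_female Number of females among them.
#' @param ages Target scan ages (days post-conception).
#' @param scans_per_age Scans contributing to each age group; the total is
#'   the cohort scan count.
#' @param jitter_days Maximum absolute deviation from the target age.
#' @param max_scans_per_subject Longitudinal cap per fetus.
#' @return A \code{cohort_design} list.
#' @export
cohort_design <- function(n_subjects = atlas_design()$n_subjects,
                          n_female = atlas_design()$n_female,
                          ages = atlas_design()$ages,
                          scans_per_age = atlas_design()$scans_per_age,
                          jitter_days = 7,
                          max_scans_per_subject = 4L) {
  stopifnot(length(ages) == length(scans_per_age),
            n_female <= n_subjects,
            sum(scans_per_age) >= n_subjects,
            sum(scans_per_age) <= n_subjects * max_scans_per_subject)
  structure(list(n_subjects = as.integer(n_subjects),
                 n_female = as.integer(n_female),
                 ages = ages, scans_per_age = as.integer(scans_per_age),
                 jitter_days = jitter_days,
                 max_scans_per_subject = as.integer(max_scans_per_subject)),
            class = "cohort_design")
}

# Allocate scans to subjects: every subject gets at least one scan, nobody
# exceeds the longitudinal cap, per-age totals are met exactly, and no
# subject is scanned twice at the same target age. Returns a data frame
# (subject index, age index).
.allocate_scans <- function(design) {
  n <- design$n_subjects
  counts <- design$scans_per_age
  n_ages <- length(counts)
  scan_count <- integer(n)
  in_age <- matrix(FALSE, n, n_ages)
  subj <- integer(0); agei <- integer(0)
  remaining <- counts
  # first pass: one scan each, age groups drawn proportionally to remaining
  for (s in sample.int(n)) {
    a <- sample.int(n_ages, 1L, prob = pmax(remaining, 0) + 1e-9)
    subj <- c(subj, s); agei <- c(agei, a)
    scan_count[s] <- scan_count[s] + 1L
    in_age[s, a] <- TRUE
    remaining[a] <- remaining[a] - 1L
  }
  # second pass: fill each age group from eligible subjects
  for (a in order(remaining, decreasing = TRUE)) {
    while (remaining[a] > 0L) {
      elig <- which(scan_count < design$max_scans_per_subject & !in_age[, a])
      if (!length(elig)) stop("scan allocation infeasible", call. = FALSE)
      # favor subjects with fewer scans to keep the design mixed-longitudinal
      w <- (design$max_scans_per_subject - scan_count[elig])^2
      s <- if (length(elig) == 1L) elig else sample(elig, 1L, prob = w)
      subj <- c(subj, s); agei <- c(agei, a)
      scan_count[s] <- scan_count[s] + 1L
      in_age[s, a] <- TRUE
      remaining[a] <- remaining[a] - 1L
    }
  }
  data.frame(subject = subj, age_index = agei)
}

#' Simulate a mixed-longitudinal fetal cohort
#'
#' Generates a long measurement table with known ground truth: per region,
#' \code{value = V(age; params_sex) + subject_intercept + noise}, where
#' \code{V} is the region's generative growth curve, the subject intercept
#' is a Gaussian random effect shared across a fetus's scans, and the noise
#' is independent Gaussian measurement error. Noise is heteroscedastic with
#' standard deviation \code{noise_frac} of the age-specific model value;
#' the subject intercept SD is \code{subject_frac} of the region's value at
#' the mid-study age (G122). An optional sex-by-age slope excess
#' (\code{sex_effect}, mL/day, added as \code{delta * age} for males) lets
#' simulations isolate an interaction effect on top of a pooled curve.
#'
#' Confound columns (scanner, recon, scan_number, resolution, sequence) are
#' emitted; by default they are independent of the measurements, and
#' \code{confound_effects} can add a per-level offset to induce an
#' association.
#'
#' @param design A \code{\link{cohort_design}}.
#' @param models Generative model table in the format of
#'   \code{\link{atlas_growth_parameters}}.
#' @param noise_frac Measurement noise SD as a fraction of the age-specific
#'   model value (default 0.02).
#' @param subject_frac Random-intercept SD as a fraction of the region value
#'   at G122 (default 0.04).
#' @param sex_effect Optional named vector, region -> male age-slope excess
#'   in mL/day.
#' @param confound_effects Optional named list, confound column -> named
#'   numeric offset per level.
#' @param seed Integer seed; fixed seeds reproduce the table exactly.
#' @return Data frame \code{subject, sex, age_days, region, value} plus the
#'   confound columns, with attribute \code{"truth"} recording the
#'   generative settings.
#' @export
simulate_cohort <- function(design = cohort_design(),
                            models = atlas_growth_parameters(),
                            noise_frac = 0.02, subject_frac = 0.04,
                            sex_effect = NULL, confound_effects = NULL,
                            seed = 1L) {
  stopifnot(inherits(design, "cohort_design"))
  if (!all(models$family %in% growth_families())) {
    stop("unknown model family in generative table", call. = FALSE)
  }
  set.seed(seed)
  n <- design$n_subjects
  sex <- sample(rep(c("F", "M"), c(design$n_female, n - design$n_female)))
  alloc <- .allocate_scans(design)
  jit <- sample(seq(-design$jitter_days, design$jitter_days), nrow(alloc),
                replace = TRUE)
  alloc$age_days <- design$ages[alloc$age_index] + jit
  alloc <- alloc[order(alloc$subject, alloc$age_days), ]

  scanner <- sample(c("TRIO", "PRISMA"), nrow(alloc), replace = TRUE)
  recon <- ifelse(scanner == "PRISMA", "deconv", "btk")
  resolution <- ifelse(recon == "deconv", 0.5, 0.66)
  sequence <- sample(c("TSE", "HASTE"), nrow(alloc), replace = TRUE)
  scan_number <- stats::ave(seq_len(nrow(alloc)), alloc$subject,
                            FUN = seq_along)

  regions <- unique(models$region)
  out <- vector("list", length(regions))
  for (ri in seq_along(regions)) {
    reg <- regions[ri]
    rows <- models[models$region == reg, , drop = FALSE]
    pick <- function(sx) {
      r <- rows[rows$sex == sx, , drop = FALSE]
      if (!nrow(r)) r <- rows[rows$sex == "both", , drop = FALSE]
      r[1, , drop = FALSE]
    }
    model_of <- list(F = pick("F"), M = pick("M"))
    npar <- function(m) .family_info(m$family)$n_params
    evalm <- function(m, t) {
      eval_growth_model(m$family,
                        as.numeric(m[paste0("p", seq_len(npar(m)))]), t)
    }
    ref_val <- mean(vapply(model_of, function(m) evalm(m, 122), numeric(1)))
    b_subj <- stats::rnorm(n, 0, subject_frac * abs(ref_val))
    sx <- sex[alloc$subject]
    mu <- numeric(nrow(alloc))
    for (s in c("F", "M")) {
      i <- sx == s
      mu[i] <- evalm(model_of[[s]], alloc$age_days[i])
    }
    if (!is.null(sex_effect) && reg %in% names(sex_effect)) {
      mu <- mu + sex_effect[[reg]] * alloc$age_days * (sx == "M")
    }
    val <- mu + b_subj[alloc$subject] +
      stats::rnorm(nrow(alloc), 0, noise_frac * abs(mu))
    tab <- data.frame(subject = sprintf("S%03d", alloc$subject), sex = sx,
                      age_days = alloc$age_days, region = reg, value = val,
                      scanner = scanner, recon = recon,
                      scan_number = scan_number, resolution = resolution,
                      sequence = sequence, stringsAsFactors = FALSE)
    if (!is.null(confound_effects)) {
      for (cc in names(confound_effects)) {
        off <- confound_effects[[cc]]
        tab$value <- tab$value + off[as.character(tab[[cc]])]
      }
    }
    out[[ri]] <- tab
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "truth") <- list(models = models, noise_frac = noise_frac,
                             subject_frac = subject_frac,
                             sex_effect = sex_effect, seed = seed)
  res
}

#' Simulate null residual series for calibration studies
#'
#' Draws residual-scale data with a per-subject random intercept and no
#' covariate effect (all fixed effects zero), on the sampling layout of a
#' cohort design. Used to measure the type-I error of the residual LMM
#' interaction test.
#'
#' @param design A \code{\link{cohort_design}}.
#' @param var_subject,var_resid Variance components of the generative model.
#' @param seed Integer seed.
#' @return Data frame \code{subject, sex, age_days, resid}.
#' @export
simulate_null_residuals <- function(design = cohort_design(),
                                    var_subject = 1, var_resid = 1,
                                    seed = 1L) {
  set.seed(seed)
  n <- design$n_subjects
  sex <- sample(rep(c("F", "M"), c(design$n_female, n - design$n_female)))
  alloc <- .allocate_scans(design)
  alloc$age_days <- design$ages[alloc$age_index] +
    sample(seq(-design$jitter_days, design$jitter_days), nrow(alloc),
           replace = TRUE)
  b <- stats::rnorm(n, 0, sqrt(var_subject))
  data.frame(subject = sprintf("S%03d", alloc$subject),
             sex = sex[alloc$subject],
             age_days = alloc$age_days,
             resid = b[alloc$subject] +
               stats::rnorm(nrow(alloc), 0, sqrt(var_resid)))
}
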