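#' Published growth-trajectory parameters for the fetal macaque atlas
#'
#' Fitted growth-curve parameters for the major compartments of the ONPRC
#' fetal macaque brain atlas, used as the default generative models of the
#' synthetic cohort simulator. Whole brain, cortical plate, and cerebellum
#' carry sex-specific three-parameter logistic fits (sex differences reach
#' significance there); nascent white matter is four-parameter logistic and
#' subcortical gray matter and brainstem are Gompertz, reported through
#' their descriptor form (asymptote, maximal rate, inflection age) and
#' converted back to native \code{(a, b, c)} parameters here. Ventricles
#' follow a shallow U-shaped quadratic; extra-axial CSF is a logistic
#' filler so that intracranial volume can be simulated. Units: mL and days
#' post-conception.
#'
#' @return Data frame with columns \code{region, sex} ("M", "F", or "both"),
#'   \code{family}, and \code{p1..p4} (parameters in the family's canonical
#'   order).
#' @export
atlas_growth_parameters <- function() {
  g_sub <- gompertz_from_descriptors(4.55, 0.0552, 111)
  g_bst <- gompertz_from_descriptors(3.19, 0.0166, 135)
  df <- rbind(
    data.frame(region = "whole_brain", sex = "M", family = "logistic3",
               p1 = 48.5, p2 = 0.0566, p3 = 113, p4 = NA),
    data.frame(region = "whole_brain", sex = "F", family = "logistic3",
               p1 = 48.0, p2 = 0.0533, p3 = 116, p4 = NA),
    data.frame(region = "cortical_plate", sex = "M", family = "logistic3",
               p1 = 24.1, p2 = 0.0589, p3 = 120, p4 = NA),
    data.frame(region = "cortical_plate", sex = "F", family = "logistic3",
               p1 = 24.0, p2 = 0.0561, p3 = 123, p4 = NA),
    data.frame(region = "cerebellum", sex = "M", family = "logistic3",
               p1 = 3.78, p2 = 0.0499, p3 = 141, p4 = NA),
    data.frame(region = "cerebellum", sex = "F", family = "logistic3",
               p1 = 3.10, p2 = 0.0533, p3 = 137, p4 = NA),
    # order (A, B, Rg, tmid); B (value at t = 0) is not published, a small
    # positive offset is assumed
    data.frame(region = "nascent_white_matter", sex = "both",
               family = "logistic4", p1 = 14.3, p2 = 1.5, p3 = 0.109,
               p4 = 108),
    data.frame(region = "subcortical_gray", sex = "both", family = "gompertz",
               p1 = g_sub["a"], p2 = g_sub["b"], p3 = g_sub["c"], p4 = NA),
    data.frame(region = "brainstem", sex = "both", family = "gompertz",
               p1 = g_bst["a"], p2 = g_bst["b"], p3 = g_bst["c"], p4 = NA),
    # U-shaped ventricular trajectory: minimum near G110-G116, recrossing
    # its G85 value late in gestation
    data.frame(region = "ventricles", sex = "both", family = "quadratic",
               p1 = 0.85 + 2.6e-4 * 116^2, p2 = -2 * 2.6e-4 * 116,
               p3 = 2.6e-4, p4 = NA),
    data.frame(region = "extra_axial_csf", sex = "both", family = "logistic3",
               p1 = 23, p2 = 0.045, p3 = 125, p4 = NA)
  )
  rownames(df) <- NULL
  df
}

#' Atlas template summary measures
#'
#' Whole-brain and intracranial summary values of the fetal and young-adult
#' atlas templates, plus hemispheric surface-area and thickness endpoints:
#' the inputs to the summary arithmetic (mean daily growth, percent of
#' adult, fold changes) reported with the atlas.
#'
#' @return Named list of reference values (mL, cm^2, mm, days).
#' @export
atlas_reference_values <- function() {
  list(
    whole_brain_g85_ml = 7.8,
    whole_brain_g155_ml = 42.3,
    whole_brain_adult_ml = 69.9,
    icv_g155_ml = 60.8,
    icv_adult_ml = 92.9,
    age_g85_days = 85,
    age_g155_days = 155,
    surface_area_g85_cm2 = c(F = 11.9, M = 11.7),
    surface_area_g155_cm2 = c(F = 64.8, M = 67.4),
    thickness_g85_mm = 1.10,
    thickness_g155_mm = 1.56,
    adult_age_days = 1770  # 165-day term + ~4.4 years
  )
}

#' Target fetal scan ages and per-age scan counts of the atlas design
#'
#' The mixed-longitudinal atlas design clusters scans around seven target
#' gestational ages (+/- 7 days); templates were built from 31, 5, 20, 6,
#' 28, 6, and 9 scans respectively (105 scans of 50 fetuses, 28 female).
#'
#' @return List with \code{ages}, \code{scans_per_age}, \code{n_subjects},
#'   \code{n_female}.
#' @export
atlas_design <- function() {
  list(
    ages = c(85, 97, 110, 122, 135, 147, 155),
    scans_per_age = c(31L, 5L, 20L, 6L, 28L, 6L, 9L),
    n_subjects = 50L,
    n_female = 28L
  )
}
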