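# End-to-end orchestration: volumes -> growth fits -> residual inference,
# and labels -> surfaces -> metrics -> expansion maps. The numbered scripts
# under analysis/ are thin drivers over these two entry points.

#' Configuration for the volumetric analysis pipeline
#'
#' @param table Long measurement table (data frame) or path to a CSV with
#'   header \code{subject,sex,age_days,region,value}; NULL simulates the
#'   default synthetic cohort with \code{seed}.
#' @param regions Regions to analyze (default: all in the table).
#' @param covariate Fixed covariate for the residual analysis.
#' @param confounds Confound columns to screen (set NULL to skip).
#' @param adult_volumes Optional named vector of adult volumes (mL) keyed by
#'   region, enabling percent-of-adult fits.
#' @param alpha Significance level.
#' @param seed Seed for the simulated cohort when \code{table} is NULL.
#' @param out_dir Optional directory for the JSON + TSV report.
#' @return A validated config list.
#' @export
volumetric_config <- function(table = NULL, regions = NULL,
                              covariate = "sex",
                              confounds = c("scanner", "recon",
                                            "scan_number", "resolution",
                                            "sequence"),
                              adult_volumes = NULL, alpha = 0.05,
                              seed = 1L, out_dir = NULL) {
  stopifnot(alpha > 0, alpha < 1)
  structure(list(table = table, regions = regions, covariate = covariate,
                 confounds = confounds, adult_volumes = adult_volumes,
                 alpha = alpha, seed = seed, out_dir = out_dir),
            class = "volumetric_config")
}

#' Run the volumetric analysis pipeline
#'
#' Per region: BIC model selection over the five growth families, derived
#' growth descriptors for sigmoid winners, residual covariate analysis with
#' Bonferroni correction across regions, optional confound screen and
#' percent-of-adult constrained fits. Deterministic for a fixed config.
#'
#' @param config A \code{\link{volumetric_config}}.
#' @return A report list: \code{regions} (per-region fits/descriptors),
#'   \code{effects} (coefficient summary), \code{confounds},
#'   \code{percent_of_adult}, and the config used. Written as
#'   \code{report.json} and \code{effects.tsv} when \code{out_dir} is set.
#' @export
run_volumetric_analysis <- function(config = volumetric_config()) {
  stopifnot(inherits(config, "volumetric_config"))
  tab <- config$table
  if (is.null(tab)) {
    tab <- simulate_cohort(seed = config$seed)
  } else if (is.character(tab)) {
    tab <- utils::read.csv(tab, stringsAsFactors = FALSE)
  }
  need <- c("subject", "sex", "age_days", "region", "value")
  if (!all(need %in% names(tab))) {
    stop("measurement table must have columns ",
         paste(need, collapse = ","), call. = FALSE)
  }
  regions <- config$regions
  if (is.null(regions)) {
    regions <- intersect(volume_regions(), unique(tab$region))
    if (!length(regions)) regions <- unique(tab$region)
  }
  unknown <- setdiff(regions, unique(tab$region))
  if (length(unknown)) {
    stop("regions not in table: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }

  region_reports <- list()
  selections <- list()
  for (reg in regions) {
    rows <- tab[tab$region == reg, ]
    sel <- select_growth_model(rows$age_days, rows$value)
    selections[[reg]] <- sel
    win <- sel$fits[[sel$winner]]
    rep_i <- list(family = sel$winner,
                  params = as.list(win$params),
                  bic_table = as.list(sel$bic_table))
    if (sel$winner %in% c("logistic3", "logistic4", "gompertz")) {
      rep_i <- c(rep_i, derived_descriptors(win))
    }
    region_reports[[reg]] <- rep_i
  }

  m <- length(regions)
  effects <- lapply(regions, function(r) {
    residual_effect_analysis(tab, r, selections[[r]],
                             covariate = config$covariate, m = m)
  })
  names(effects) <- regions
  eff_tab <- do.call(rbind, lapply(effects, function(x) {
    cbind(region = x$region, x$coefficients)
  }))
  rownames(eff_tab) <- NULL

  conf_rep <- NULL
  if (!is.null(config$confounds) &&
      all(config$confounds %in% names(tab))) {
    conf_rep <- lapply(regions, function(r) {
      scr <- confound_screen(tab, r, selections[[r]],
                             confounds = config$confounds, m = m)
      lapply(scr, function(x) x$coefficients)
    })
    names(conf_rep) <- regions
  }

  pct_rep <- NULL
  if (!is.null(config$adult_volumes)) {
    pct_rep <- list()
    for (reg in intersect(regions, names(config$adult_volumes))) {
      rows <- tab[tab$region == reg, ]
      pct <- percent_of_adult(rows$value, config$adult_volumes[[reg]])
      fit <- fit_percent_of_adult(rows$age_days, pct)
      pct_rep[[reg]] <- list(
        Rg = unname(fit$params["Rg"]), tmid = unname(fit$params["tmid"]),
        r_max_percent_per_day = fit$r_max_percent_per_day,
        converged = fit$converged)
    }
  }

  report <- list(regions = region_reports, effects = eff_tab,
                 confounds = conf_rep, percent_of_adult = pct_rep,
                 n_obs = nrow(tab), config = config[setdiff(names(config),
                                                            "table")])
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report[c("regions", "percent_of_adult")],
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.table(eff_tab, file.path(config$out_dir, "effects.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  report
}

#' Run the surface analysis pipeline
#'
#' From a sequence of label volumes: mid-cortical surface extraction and
#' global metrics (surface area, K*, thickness) per age, plus a monotone-K*
#' flag across ages. From a mesh correspondence set: expansion maps to the
#' reference age, vertex-wise logistic trajectory maps, and stage-wise mean
#' expansion differences.
#'
#' @param label_volumes Named list (age -> \code{label_volume}) or NULL.
#' @param cset Correspondence set (see
#'   \code{\link{make_growing_mesh_sequence}}) or NULL.
#' @param hemisphere Hemisphere passed to the extraction.
#' @param reference_age Reference for expansion maps (default: first age of
#'   the set).
#' @param out_dir Optional directory for CSV outputs.
#' @return List with \code{metrics} (per-age data frame),
#'   \code{k_star_monotone}, \code{expansion} (maps matrix),
#'   \code{trajectories} (\code{expansion_trajectory_maps}),
#'   \code{mean_differences}.
#' @export
run_surface_analysis <- function(label_volumes = NULL, cset = NULL,
                                 hemisphere = "both", reference_age = NULL,
                                 out_dir = NULL) {
  metrics <- NULL; kmono <- NA
  if (!is.null(label_volumes)) {
    rows <- lapply(names(label_volumes), function(age) {
      vol <- label_volumes[[age]]
      mesh <- extract_midcortical_surface(vol, hemisphere)
      cp_ml <- compartment_volumes(vol)[["cortical_plate"]]
      sm <- surface_metrics(mesh, cp_ml)
      data.frame(age_days = as.numeric(age),
                 surface_area_cm2 = sm$surface_area_cm2,
                 k_star = sm$k_star, thickness_mm = sm$thickness_mm)
    })
    metrics <- do.call(rbind, rows)
    metrics <- metrics[order(metrics$age_days), ]
    kmono <- !is.unsorted(metrics$k_star)
  }
  expansion <- NULL; traj <- NULL; mdiff <- NULL
  if (!is.null(cset)) {
    if (is.null(reference_age)) reference_age <- cset$ages[1]
    expansion <- expansion_to_reference(cset, reference_age)
    traj <- fit_expansion_trajectories(expansion, cset$ages)
    ref_mesh <- cset$meshes[[match(reference_age, cset$ages)]]
    nm <- colnames(expansion)
    mdiff <- stats::setNames(vapply(seq_len(ncol(expansion) - 1), function(i) {
      mean_expansion_difference(expansion[, i], expansion[, i + 1], ref_mesh)
    }, numeric(1)), paste(nm[-ncol(expansion)], nm[-1], sep = "_to_"))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(metrics)) {
      utils::write.csv(metrics, file.path(out_dir, "surface_metrics.csv"),
                       row.names = FALSE)
    }
    if (!is.null(traj)) {
      utils::write.csv(
        data.frame(A = traj$A_map, Rg = traj$Rg_map, tmid = traj$tmid_map,
                   converged = traj$converged),
        file.path(out_dir, "expansion_trajectories.csv"), row.names = FALSE)
    }
  }
  list(metrics = metrics, k_star_monotone = kmono, expansion = expansion,
       trajectories = traj, mean_differences = mdiff)
}
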