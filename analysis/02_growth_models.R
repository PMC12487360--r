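#!/usr/bin/env Rscript
# Growth-trajectory modeling: for each compartment of the simulated cohort,
# fit the five candidate families (linear, quadratic, 3PL, 4PL, Gompertz),
# select by BIC, and derive the growth descriptors (inflection age tmid,
# maximal rate, asymptote). Whole-brain volumes are additionally expressed
# as percent of the adult value and refit with the asymptote pinned at 100%
# to locate the age of maximal relative growth.

library(fetalgrowth)

tab <- read.csv("results/cohort.csv", stringsAsFactors = FALSE)
ref <- atlas_reference_values()

cfg <- volumetric_config(table = tab,
                         confounds = NULL,
                         adult_volumes = c(whole_brain =
                                             ref$whole_brain_adult_ml),
                         out_dir = "results")
report <- run_volumetric_analysis(cfg)

cat("BIC-selected growth family per region:\n")
rows <- lapply(names(report$regions), function(r) {
  b <- report$regions[[r]]
  data.frame(region = r, family = b$family,
             t_mid = if (!is.null(b$t_mid)) round(b$t_mid, 1) else NA,
             r_max = if (!is.null(b$r_max)) signif(b$r_max, 3) else NA,
             asymptote = if (!is.null(b$asymptote))
               round(b$asymptote, 2) else NA)
})
fit_tab <- do.call(rbind, rows)
print(fit_tab, row.names = FALSE)
write.csv(fit_tab, "results/growth_parameters.csv", row.names = FALSE)

pw <- report$percent_of_adult$whole_brain
cat(sprintf(
  "\nWhole brain percent-of-adult fit (A pinned at 100%%):\n  maximal growth %.2f %%/day at G%.0f\n",
  pw$r_max_percent_per_day, pw$tmid))
cat("Wrote results/report.json, results/growth_parameters.csv\n")
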