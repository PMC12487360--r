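#!/usr/bin/env Rscript
# Two-stage sex-difference inference: residuals from each region's
# BIC-selected population growth curve are analyzed with a random-intercept
# linear mixed model (sex, age, and their interaction as fixed effects,
# fetus as random effect; Satterthwaite df), with Bonferroni correction
# across the seven regions. Potential acquisition confounds (scanner,
# reconstruction, scan number, resolution, pulse sequence) are screened the
# same way for the whole brain.

library(fetalgrowth)

tab <- read.csv("results/cohort.csv", stringsAsFactors = FALSE)

effects <- region_effect_table(tab, regions = volume_regions())
summ <- attr(effects, "summary")
write.table(summ, "results/sex_effects.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

inter <- summ[summ$term == "age:covM", ]
cat("Age-by-sex interactions (male slope excess, mL/day):\n")
print(inter[, c("region", "estimate", "se", "df", "p", "p_bonferroni",
                "significant")], row.names = FALSE, digits = 3)
sig <- inter$region[inter$significant]
cat(if (length(sig)) {
  paste("Interactions surviving Bonferroni correction:",
        paste(sig, collapse = ", "), "\n")
} else "No interaction survives Bonferroni correction in this cohort\n")

scr <- confound_screen(tab, "whole_brain", m = length(volume_regions()))
conf_p <- sapply(scr, function(x) min(x$coefficients$p[3:4]))
cat("\nConfound screen (whole brain, smallest uncorrected p across the\n")
cat("confound main effect and its age interaction):\n")
print(round(conf_p, 3))
cat("Note: scan number tracks age within fetus in a longitudinal design,\n")
cat("so it can absorb residual lack-of-fit of the pooled growth curve\n")
cat("(here driven by the simulated sex-specific trajectories); the\n")
cat("acquisition confounds proper (scanner, recon, resolution, sequence)\n")
cat("are independent of the measurements, as simulated.\n")
cat("Wrote results/sex_effects.tsv\n")
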