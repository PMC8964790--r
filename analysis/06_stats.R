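#!/usr/bin/env Rscript
# Group statistics: two-way ANOVA (fatigue level x task) with partial
# eta squared on every band x ROI-pair connectivity strength and on the
# network metrics, with Tukey-Kramer post-hoc comparisons where the
# level main effect is significant without an interaction.

source(file.path("analysis", "00_config.R"))

sessions <- generate_study(study, species = "HbO")
lab <- label_fatigue(sessions, seed = derive_seed(MASTER_SEED, "label"))

tab <- study_metric_table(sessions, species = "HbO")
# analyse by the assigned (score-based) levels, as the original workflow does
tab$level <- lab$scores$level[match(tab$participant_id,
                                    lab$scores$participant_id)]

cmp <- band_metric_comparison(tab)
utils::write.csv(cmp$anova, out_path("anova.csv"), row.names = FALSE)
if (!is.null(cmp$posthoc))
  utils::write.csv(cmp$posthoc, out_path("posthoc.csv"), row.names = FALSE)

lev <- cmp$anova[cmp$anova$effect == "level", ]
cat("Significant level main effects (p < 0.05) per band:\n")
print(table(lev$band[lev$p < 0.05]))
c3 <- lev[lev$band == "III" & lev$target == "C", ]
cat(sprintf("\nBand III clustering coefficient: F = %.2f, p = %.4g, partial eta^2 = %.3f\n",
            c3$F, c3$p, c3$partial_eta2))
if (!is.null(cmp$posthoc)) {
  ph <- cmp$posthoc[cmp$posthoc$band == "III" & cmp$posthoc$target == "C", ]
  if (nrow(ph)) {
    cat("Tukey-Kramer on band-III clustering:\n")
    print(ph[, c("group1", "group2", "diff", "se", "p")], row.names = FALSE)
  }
}
cat("Wrote", out_path("anova.csv"),
    if (!is.null(cmp$posthoc)) paste("and", out_path("posthoc.csv")), "\n")
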