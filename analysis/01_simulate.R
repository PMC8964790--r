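#!/usr/bin/env Rscript
# Simulate the synthetic fatigue study and write its questionnaire and
# behavioural tables. Hemoglobin recordings are deterministic functions
# of the design seed and are regenerated on demand by later scripts, so
# they are not stored.

source(file.path("analysis", "00_config.R"))

sessions <- generate_study(study, species = NULL)

write_mfi_table(sessions, out_path("mfi.csv"))
write_nback_table(sessions, out_path("nback.csv"))

lev <- vapply(sessions, `[[`, "", "fatigue_level")
task <- vapply(sessions, `[[`, "", "task")
cat(sprintf("Simulated %d sessions (%d per task x level cell).\n",
            length(sessions), study$n_per_cell))
print(table(level = lev, task = task))
mfi <- vapply(sessions, function(s) mfi_score(s$mfi_items), 0)
beh <- vapply(sessions, function(s) behavior_score(s$nback), 0)
for (l in c("L1", "L2", "L3"))
  cat(sprintf("%s: MFI %.2f +- %.2f, n-back score %.2f +- %.2f\n",
              l, mean(mfi[lev == l]), sd(mfi[lev == l]),
              mean(beh[lev == l]), sd(beh[lev == l])))
cat("Wrote", out_path("mfi.csv"), "and", out_path("nback.csv"), "\n")
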