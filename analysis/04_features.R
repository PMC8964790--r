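#!/usr/bin/env Rscript
# Assemble the 2,250-dimensional per-session feature table:
# 420 ROI-pair correlations + 30 network metrics + 1,800 time-domain
# features over 3 hemoglobin species x 5 bands.

source(file.path("analysis", "00_config.R"))

sessions <- generate_study(study)
cat(sprintf("Extracting features for %d sessions ...\n", length(sessions)))
feat <- study_features(sessions)
utils::write.csv(feat, out_path("features.csv"), row.names = FALSE)

stopifnot(ncol(feat) == 4 + 2250, !anyNA(feat))
cat(sprintf("Feature table: %d sessions x %d features (+4 metadata).\n",
            nrow(feat), ncol(feat) - 4))
blocks <- c(fc = 420, net = 30, td = 1800)
for (b in names(blocks))
  cat(sprintf("  %-3s block: %d features\n", b,
              sum(grepl(paste0("\\|", b, "\\|"), names(feat)))))
cat("Wrote", out_path("features.csv"), "\n")
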