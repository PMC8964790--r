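#!/usr/bin/env Rscript
# Band decomposition and entropy-weighted ROI aggregation, illustrated on
# one session: writes the five band-wise ROI time series and the entropy
# weights of every ROI's channels.

source(file.path("analysis", "00_config.R"))

ses <- generate_session(study, "example", "PVT", "L1", species = "HbO")
rec <- ses$recordings$HbO
cat(sprintf("Example session: %d samples x %d channels at %g Hz.\n",
            nrow(rec$samples), length(rec$channel_ids), rec$fs))

series <- roi_aggregate(rec)
for (b in names(series)) {
  df <- as.data.frame(series[[b]]$y)
  utils::write.csv(signif(df, 8), out_path(sprintf("roi_series_band%s.csv", b)),
                   row.names = FALSE)
}

# entropy weights per ROI in band III (the myogenic band)
m <- default_montage()
bIII <- default_bands()["III"]
filt <- bandpass(rec$samples, bIII$III, rec$fs)
rows <- lapply(m$roi_order, function(roi) {
  cols <- match(m$roi_channels[[roi]], rec$channel_ids)
  ew <- entropy_weights(filt[, cols, drop = FALSE])
  data.frame(roi = roi, channel = m$roi_channels[[roi]],
             entropy = unname(ew$entropy), weight = unname(ew$weights))
})
wtab <- do.call(rbind, rows)
utils::write.csv(wtab, out_path("entropy_weights_bandIII.csv"),
                 row.names = FALSE)

cat("Entropy weights are near-uniform within ROIs on homogeneous synthetic",
    "channels:\n")
print(aggregate(weight ~ roi, wtab, function(w)
  sprintf("%.2f-%.2f", min(w), max(w))))
cat("Wrote per-band ROI series and", out_path("entropy_weights_bandIII.csv"),
    "\n")
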