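# Shared configuration for the numbered analysis scripts.
#
# Every script is a stand-alone driver: it regenerates what it needs from
# the master seed (recordings are deterministic functions of the design
# seed, so nothing bulky is stored on disk) and writes its tables under
# results/.

library(fatiguenet)

MASTER_SEED <- 20250901
RESULTS_DIR <- file.path("results")
dir.create(RESULTS_DIR, recursive = TRUE, showWarnings = FALSE)

# The default design: 12 sessions per (task x level) cell = 108 sessions,
# mirroring a 36-participant cohort tested three times; 600 s at 16 Hz.
study <- study_design(seed = MASTER_SEED)

out_path <- function(...) file.path(RESULTS_DIR, ...)
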