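# Shared settings for the analysis scripts. Every script regenerates what it
# needs deterministically from this seed, so the workflow can be run
# script-by-script without passing large image files around.

library(neurocomp)

ANALYSIS_SEED <- 20260101L
OUT <- "results"
dir.create(OUT, recursive = TRUE, showWarnings = FALSE)

analysis_spec <- function() {
  cohort_spec(n_carriers = 106L, n_controls = 111L)
}

analysis_truth <- function() {
  ground_truth(seed = ANALYSIS_SEED)
}
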