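# Small fixture builders shared across test files.

suppressPackageStartupMessages(library(SummarizedExperiment))

# Minimal ROI annotation table for a nested patient/tumor/ROI hierarchy.
makeAnn <- function(nPatients, tumorsPerPatient, roisPerTumor) {
  rows <- expand.grid(r = seq_len(roisPerTumor),
                      t = seq_len(tumorsPerPatient),
                      p = seq_len(nPatients))
  data.frame(
    roi_id = sprintf("P%02d_T%d_R%d", rows$p, rows$t, rows$r),
    patient_id = sprintf("P%02d", rows$p),
    tumor_id = sprintf("P%02d_T%d", rows$p, rows$t),
    stringsAsFactors = FALSE)
}

# ProbeCountSet from an explicit count matrix and a probes-per-gene map.
makeProbeSet <- function(counts, targetId, isNegative) {
  ProbeCountSet(counts, targetId = targetId, isNegative = isNegative)
}

# A tiny cohort + RNA panel, fast enough for per-test generation.
smallCohortData <- function(seed = 11L, nPatients = 6L,
                            assignment = NULL, ...) {
  cfg <- cohortConfig(nPatients = nPatients,
                      phenotypeAssignment = assignment,
                      seed = seed, ...)
  truth <- generateCohort(cfg)
  panel <- rnaPanelConfig(nGenes = 120L, probesPerGene = 6L,
                          nNegativeProbes = 30L)
  list(truth = truth, panel = panel,
       probes = generateRnaProbeCounts(truth, panel))
}
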