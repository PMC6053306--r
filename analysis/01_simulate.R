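#!/usr/bin/env Rscript
# Stage 1 — simulate the study.
#
# Generates the synthetic two-cell-type promoter capture Hi-C study used
# by every downstream stage: an MboI-like fragment map (mean 422 bp),
# baited promoters, three replicates of distance-decaying loops per cell
# type with 20% dropout, TAD and compartment tracks, histone-peak calls
# with a 3x anchor enrichment, an LD-block haplotype panel with tag SNPs
# planted in loop anchors, eQTLs with a 50% looping preference, and
# expression coupled to compartment and local peak density. Inputs are
# written under results/bundle/ in the pipeline's exchange formats, with
# the planted truth under results/bundle/truth/.

suppressMessages(library(promloop))

seed <- as.integer(Sys.getenv("PROMLOOP_SEED", "1"))
dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

cfg <- sim_config(seed = seed)
bundle <- simulate_dataset(cfg)
write_bundle(bundle, "results/bundle")
saveRDS(bundle, "scratch/bundle.rds")  # in-memory handoff for stages 2-6

message(sprintf(
  "simulated %d fragments, %d genes, %d true loops (%.0f%% shared), %d eQTLs",
  nrow(bundle$fragment_map), nrow(bundle$tss), nrow(bundle$truth$loops),
  100 * mean(bundle$truth$loops$cell_type == "shared"),
  nrow(bundle$eqtls)))
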