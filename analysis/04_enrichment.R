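#!/usr/bin/env Rscript
# Stage 4 — chromatin-feature enrichment.
#
# Random-fragment background enrichment (100 iterations) of
# promoter-interacting distal fragments for the cell type's peaks,
# expression-binned enrichment across the five TPM groups, the 3x3
# specificity grid (cell-type-specific / shared interactions against
# cell-type-only / shared features), and the Spearman correlation of
# expression with peak density within 300 kb of the TSS.

suppressMessages({
  library(promloop)
  library(data.table)
})

bundle <- readRDS("scratch/bundle.rds")
seed <- as.integer(Sys.getenv("PROMLOOP_SEED", "1"))
pool <- background_pool(bundle$fragment_map, bundle$promoter_regions)

rows <- list()
for (ct in c("A", "B")) {
  cons <- fread(sprintf("results/consensus_%s.tsv", ct))
  distal <- distal_fragment_table(cons, bundle$fragment_map)
  r <- enrichment(distal, bundle$peaks[[ct]], pool, iterations = 100,
                  seed = seed)
  message(sprintf("%s: observed %.3f vs null %.3f -> fold %.2f (Z = %.1f)",
                  ct, r$observed, r$null_mean, r$fold, r$z))
  rows[[ct]] <- c(list(cell_type = ct, n_fragments = nrow(distal)), r)

  tpm <- bundle$tpm[[ct]]
  tpm_mean <- tpm[, .(gene, tpm = rowMeans(.SD)), .SDcols = -"gene"]
  be <- binned_enrichment(tpm_mean, cons, bundle$peaks[[ct]], pool,
                          bundle$fragment_map, iterations = 100,
                          seed = seed)
  fwrite(be, sprintf("results/enrichment_bins_%s.tsv", ct), sep = "\t")

  pc <- peak_density_expression_corr(
    tpm_mean, bundle$peaks[[ct]], bundle$tss,
    genes_with_interactions = unique(cons$gene))
  message(sprintf("  expression ~ peak density within 300 kb: rho = %.2f (p = %.2g, n = %d)",
                  pc$rho, pc$p, pc$n))
}
fwrite(rbindlist(rows), "results/enrichment_overall.tsv", sep = "\t")

consA <- fread("results/consensus_A.tsv")
consB <- fread("results/consensus_B.tsv")
sets <- list(A_specific = consA[specificity == "specific"],
             B_specific = consB[specificity == "specific"],
             shared = consB[specificity == "shared"])
grid <- specificity_matrix(sets, bundle$peaks$A, bundle$peaks$B, pool,
                           bundle$fragment_map, iterations = 100,
                           seed = seed)
fwrite(grid, "results/specificity_grid.tsv", sep = "\t")
print(dcast(as.data.table(grid), feature_class ~ interaction_class,
            value.var = "fold"))
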