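#!/usr/bin/env Rscript
# Stage 6 — permutation and resampling statistics.
#
# (i) eQTL-loop enrichment: are promoter-distal eQTLs more likely than
# chance to fall inside an interaction of their own associated gene? The
# null re-maps each promoter's interactions to a different promoter
# (within-chromosome derangement), preserving distance and strand.
# (ii) Gene-set resampling: are linked target genes over-represented in
# an annotated phenotype set, against random draws from all genes with a
# promoter-distal interaction?
# (iii) GO enrichment with parent propagation on a toy ontology built
# from the planted compartment classes, as a smoke demonstration.

suppressMessages({
  library(promloop)
  library(data.table)
})

bundle <- readRDS("scratch/bundle.rds")
seed <- as.integer(Sys.getenv("PROMLOOP_SEED", "1"))
consB <- fread("results/consensus_B.tsv")

eq <- filter_eqtls(bundle$eqtls, bundle$promoter_regions, bundle$tss)
r <- eqtl_loop_enrichment(eq, consB, bundle$tss, bundle$layout,
                          n_perm = 1000, seed = seed)
message(sprintf(
  "eQTL-own-gene proportion: observed %.3f vs permuted %.3f +- %.3f (Z = %.1f, empirical p = %.3g)",
  r$observed, r$null_mean, r$null_sd, r$z, r$p_empirical))
fwrite(data.table(observed = r$observed, null_mean = r$null_mean,
                  null_sd = r$null_sd, z = r$z, p = r$p,
                  p_empirical = r$p_empirical, seed = r$seed),
       "results/eqtl_enrichment.tsv", sep = "\t")

links <- fread("results/snp_gene_links.tsv")
eligible <- unique(consB[category != "P-promoter" | TRUE, gene])
targets <- intersect(unique(links$target_gene), eligible)
# annotated set: genes whose TSS sits in the active (A) compartment of
# cell type B — a stand-in phenotype annotation derived from the bundle
ann <- assign_compartment(bundle$tss, bundle$compartments$B)
annotated <- ann[compartment == "A", gene]
if (length(targets) >= 5) {
  g <- geneset_resample_enrichment(targets, eligible, annotated,
                                   n_iter = 1000, seed = seed)
  message(sprintf(
    "target genes in annotated set: observed %.2f vs null %.2f (fold %.2f, Z = %.1f)",
    g$observed, g$null_mean, g$fold, g$z))
  fwrite(as.data.table(g[c("observed", "null_mean", "null_sd", "fold",
                           "z", "p")]),
         "results/geneset_enrichment.tsv", sep = "\t")
}

# toy GO run: two terms, switching genes annotated to the child
dag <- list(terms = data.table(id = c("T:base", "T:active"),
                               name = c("all states", "active chromatin")),
            edges = data.table(id = "T:active", parent = "T:base"))
assoc <- data.table(gene = annotated, term = "T:active")
go <- go_enrichment(intersect(targets, bundle$tss$gene), bundle$tss$gene,
                    dag, assoc)
fwrite(go, "results/go_enrichment.tsv", sep = "\t")
print(go)
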