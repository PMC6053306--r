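#!/usr/bin/env Rscript
# Stage 2 — interaction calling post-processing.
#
# Applies the >= 10 kb distance filter per replicate, forms the 2-of-3
# replicate consensus with 1 kb-extension matching, splits each cell
# type's consensus into cell-type-specific and shared interactions,
# categorises distal ends (P-promoter / P-proximal / P-distal) and
# summarises span distances. Writes consensus tables and WashU longrange
# tracks under results/.

suppressMessages({
  library(promloop)
  library(data.table)
})

bundle <- readRDS("scratch/bundle.rds")
filtered <- lapply(bundle$interactions, function(reps)
  lapply(reps, filter_min_distance))
cons <- lapply(filtered, replicate_consensus)
bait_frags <- bundle$fragment_map[frag_id %in% bundle$baits$frag_id]

for (ct in names(cons)) {
  other <- setdiff(names(cons), ct)[1]
  x <- cell_type_specific(cons[[ct]], filtered[[other]])
  x[, category := categorize_interaction(x, bait_frags, bundle$tss)]
  ds <- distance_summary(x)
  message(sprintf(
    "%s: %d consensus interactions (%.0f%% specific); %s; median span %.0f kb (mean %.0f kb)",
    ct, nrow(x), 100 * mean(x$specificity == "specific"),
    paste(sprintf("%s %.0f%%", names(table(x$category)),
                  100 * prop.table(table(x$category))), collapse = ", "),
    ds$median / 1e3, ds$mean / 1e3))
  fwrite(x, sprintf("results/consensus_%s.tsv", ct), sep = "\t")
  write_washu_track(x, sprintf("results/track_%s.txt", ct))
}

tr <- truth_report(bundle, setNames(cons, names(cons)))
message(sprintf("recovery vs planted loops: A %.3f/%.3f, B %.3f/%.3f (recall/precision)",
                tr$recall_A, tr$precision_A, tr$recall_B, tr$precision_B))
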