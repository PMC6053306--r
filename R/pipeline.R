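# End-to-end orchestration over a simulated (or equivalently structured)
# bundle: every stage of the downstream analysis in dependency order,
# deterministic given the seed, with a provenance manifest. The numbered
# scripts under analysis/ are thin narrative drivers over this function
# and the stage functions it calls.

#' Run the full downstream pipeline on a bundle
#'
#' Stages, in dependency order: minimum-distance filter and replicate
#' consensus per cell type; cell-type specificity; interaction categories
#' and distance summaries; TAD classification; fragment-background peak
#' enrichment (cell type B); LD expansion and SNP-gene linking (cell type
#' B, 1 kb-extended); eQTL-loop permutation enrichment; compartment-switch
#' classification and expression tests. All outputs are written as
#' tab-separated tables under \code{outdir}, plus a JSON manifest
#' (seed, parameters, per-stage row counts).
#'
#' @param bundle bundle from [simulate_dataset()] (or assembled from real
#'   inputs with the same element names).
#' @param outdir output directory.
#' @param seed seed for every randomized stage.
#' @param n_perm permutations for the eQTL stage (default 200; the
#'   standalone stage function defaults to 1000).
#' @param iterations background iterations for enrichment (default 100).
#' @return invisible list of in-memory stage results.
#' @export
run_pipeline <- function(bundle, outdir, seed = 1L, n_perm = 200L,
                         iterations = 100L) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  res <- list(seed = seed)
  cells <- names(bundle$interactions)

  filtered <- lapply(bundle$interactions, function(reps)
    lapply(reps, filter_min_distance))
  cons <- lapply(filtered, replicate_consensus)
  res$consensus <- cons
  for (ct in cells) {
    other <- setdiff(cells, ct)[1]
    sp <- cell_type_specific(cons[[ct]], filtered[[other]])
    sp[, category := categorize_interaction(
      sp, bundle$fragment_map[frag_id %in% bundle$baits$frag_id],
      bundle$tss)]
    sp[, tad_class := classify_tad(sp, bundle$domains)]
    res$consensus[[ct]] <- sp
    fwrite(sp, file.path(outdir, sprintf("consensus_%s.tsv", ct)),
           sep = "\t")
    write_washu_track(sp, file.path(outdir, sprintf("track_%s.txt", ct)))
  }
  res$distance <- lapply(res$consensus, distance_summary)

  # enrichment of cell-type-B distal fragments for cell-type-B peaks
  pool <- background_pool(bundle$fragment_map, bundle$promoter_regions)
  distal_b <- distal_fragment_table(res$consensus$B, bundle$fragment_map)
  res$enrichment <- enrichment(distal_b, bundle$peaks$B, pool,
                               iterations = iterations, seed = seed)
  fwrite(as.data.table(res$enrichment[c("observed", "null_mean", "null_sd",
                                        "fold", "z", "p")]),
         file.path(outdir, "enrichment_B.tsv"), sep = "\t")

  # GWAS linking through 1 kb-extended B interactions
  ld <- ld_expand(bundle$tag_snps, bundle$panel)
  links <- link_snps(ld, res$consensus$B, bundle$promoter_regions)
  if (nrow(links)) links[, n_skipped := skip_count(links, bundle$tss)]
  res$ld <- ld; res$links <- links
  res$link_summary <- link_summary(links, bundle$domains)
  fwrite(links, file.path(outdir, "snp_gene_links.tsv"), sep = "\t")

  # eQTL permutation enrichment on fragment-level B interactions
  eq <- filter_eqtls(bundle$eqtls, bundle$promoter_regions, bundle$tss)
  res$eqtl <- eqtl_loop_enrichment(eq, res$consensus$B, bundle$tss,
                                   bundle$layout, n_perm = n_perm,
                                   seed = seed)
  fwrite(as.data.table(res$eqtl[c("observed", "null_mean", "null_sd",
                                  "z", "p", "p_empirical")]),
         file.path(outdir, "eqtl_enrichment.tsv"), sep = "\t")

  # compartment switches and expression
  asn <- lapply(cells, function(ct)
    assign_compartment(bundle$tss, bundle$compartments[[ct]]))
  names(asn) <- cells
  sw <- classify_switch(asn$A, asn$B)
  fc <- log2fc_from_tpm(bundle$tpm$A, bundle$tpm$B)
  res$switches <- sw
  res$switch_test <- switch_expression_test(sw, fc)
  fwrite(sw, file.path(outdir, "compartment_switches.tsv"), sep = "\t")
  fwrite(res$switch_test$summary,
         file.path(outdir, "switch_expression.tsv"), sep = "\t")

  manifest <- list(
    seed = seed, n_perm = n_perm, iterations = iterations,
    config = bundle$truth$config[
      !vapply(bundle$truth$config, is.function, logical(1))],
    rows = list(
      consensus = lapply(res$consensus, nrow),
      links = nrow(links), switches = nrow(sw))
  )
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(res)
}
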