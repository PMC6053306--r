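# Resampling and permutation statistics: eQTL-loop enrichment with
# promoter-remapped nulls, phenotype gene-set resampling, and
# hypergeometric GO enrichment with ontology parent propagation.

#' Filter eQTLs to promoter-distal records far from their associated gene
#'
#' Keeps eQTLs not inside any captured promoter region and at least
#' \code{min_bp} from their associated gene's TSS, so the eQTL could in
#' principle fall in an interaction with that gene.
#'
#' @param eqtls data.table snp, chrom, pos, gene (associated gene).
#' @param promoter_regions promoter region table.
#' @param tss_catalog TSS catalog.
#' @param min_bp minimum distance to the associated TSS (default 10000).
#' @return filtered data.table.
#' @export
filter_eqtls <- function(eqtls, promoter_regions, tss_catalog,
                         min_bp = 10000) {
  e <- as.data.table(eqtls)
  pr <- as.data.table(promoter_regions)
  tss <- as.data.table(tss_catalog)
  e <- tss[, .(gene, tss = pos)][e, on = "gene", nomatch = NULL]
  e <- e[abs(pos - tss) >= min_bp]
  inprom <- vapply(seq_len(nrow(e)), function(i)
    pr[chrom == e$chrom[i] & start <= e$pos[i] & e$pos[i] < end, .N] > 0,
    logical(1))
  e[!inprom][, tss := NULL][]
}

# signed, strand-aware offset of a distal interval from its promoter TSS:
# positive = downstream of the TSS in gene orientation
.interval_offsets <- function(cons, tssmap) {
  x <- tssmap[cons, on = "gene", nomatch = NULL]
  x[, `:=`(
    off = ifelse(strand == "+", other_start - tss, tss - other_end),
    width = other_end - other_start
  )]
  x
}

# uniform random derangement by rejection; n >= 2
.derangement <- function(n) {
  if (n < 2) stopf("derangement needs >= 2 elements")
  repeat {
    p <- sample.int(n)
    if (all(p != seq_len(n))) return(p)
  }
}

#' eQTL-loop enrichment with a promoter-remapping null
#'
#' Observed statistic: among eQTLs that overlap at least one
#' promoter-distal consensus interval (fragment-level), the proportion
#' overlapping an interval whose interaction's gene equals the eQTL's
#' associated gene. The null re-maps every promoter's interaction set to a
#' different promoter (a uniform random derangement within each
#' chromosome), preserving each interval's distance and strand orientation
#' relative to the TSS; intervals falling outside the chromosome after
#' re-mapping are dropped and the proportion recomputed.
#'
#' @param eqtls filtered eQTL table ([filter_eqtls()]).
#' @param consensus consensus interaction table.
#' @param tss_catalog TSS catalog with strand (one TSS per gene used).
#' @param layout named chromosome-length vector.
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed.
#' @param method "derangement" (default) or "redraw" (independent random
#'   re-assignment, allowing fixed points to be avoided per draw only).
#' @return list: observed, perm (vector), null_mean, null_sd, z, p
#'   (one-sided normal), p_empirical ((#perm >= obs + 1)/(n_perm + 1)),
#'   n_eqtl_overlapping, seed.
#' @export
eqtl_loop_enrichment <- function(eqtls, consensus, tss_catalog, layout,
                                 n_perm = 1000L, seed = 1L,
                                 method = c("derangement", "redraw")) {
  method <- match.arg(method)
  e <- as.data.table(eqtls)
  cons <- as.data.table(consensus)
  tssmap <- unique(as.data.table(tss_catalog)[, .(gene, chrom, tss = pos,
                                                  strand)], by = "gene")
  layout <- validate_layout(layout)

  prop_own_gene <- function(ints) {
    # ints: gene, chrom, start, end (distal intervals)
    if (!nrow(ints)) return(NA_real_)
    ik <- ints[, .(gene, chrom, start, end)]
    setkey(ik, chrom, start, end)
    sq <- e[, .(chrom, start = pos, end = pos + 1, xid = seq_len(nrow(e)))]
    h <- foverlaps(sq, ik, by.x = c("chrom", "start", "end"),
                   type = "any", nomatch = NULL)
    h <- h[i.start >= start & i.start < end]
    if (!nrow(h)) return(NA_real_)
    hit <- h[, .(own = any(gene == e$gene[xid[1]])), by = xid]
    mean(hit$own)
  }

  obs_ints <- cons[, .(gene, chrom, start = other_start, end = other_end)]
  observed <- prop_own_gene(obs_ints)
  if (is.na(observed)) {
    warnf("no eQTL overlaps any interaction; enrichment undefined")
    return(list(observed = NA_real_, perm = numeric(0), null_mean = NA,
                null_sd = NA, z = NA, p = NA, p_empirical = NA,
                n_eqtl_overlapping = 0L, seed = seed))
  }

  offs <- .interval_offsets(cons, tssmap)
  proms <- unique(offs[, .(gene, chrom)])
  single <- proms[, .N, by = chrom][N < 2]
  if (nrow(single))
    stopf(paste("chromosome(s) %s carry a single interacting promoter;",
                "promoter re-mapping needs >= 2 promoters per chromosome"),
          paste(single$chrom, collapse = ", "))

  set.seed(seed)
  perm <- numeric(n_perm)
  genes_by_chr <- split(proms$gene, proms$chrom)
  for (k in seq_len(n_perm)) {
    mapping <- rbindlist(lapply(names(genes_by_chr), function(chr) {
      g <- genes_by_chr[[chr]]
      idx <- if (method == "derangement") .derangement(length(g))
             else sample.int(length(g))
      data.table(gene = g, new_gene = g[idx])
    }))
    rem <- mapping[offs, on = "gene", nomatch = NULL]
    rem <- tssmap[, .(new_gene = gene, new_tss = tss,
                      new_strand = strand)][rem, on = "new_gene"]
    rem[, `:=`(
      start = ifelse(new_strand == "+", new_tss + off,
                     new_tss - off - width),
      end = ifelse(new_strand == "+", new_tss + off + width,
                   new_tss - off)
    )]
    rem <- rem[start >= 0 & end <= layout[chrom]]
    perm[k] <- prop_own_gene(
      rem[, .(gene = new_gene, chrom, start, end)])
  }
  perm_ok <- perm[!is.na(perm)]
  mu <- mean(perm_ok); s <- sd(perm_ok)
  z <- if (is.na(s) || s == 0) NA_real_ else (observed - mu) / s
  p <- if (is.na(z)) NA_real_ else pnorm(abs(z), lower.tail = FALSE)
  list(observed = observed, perm = perm, null_mean = mu, null_sd = s,
       z = z, p = p,
       p_empirical = (sum(perm_ok >= observed) + 1) / (n_perm + 1),
       n_eqtl_overlapping = NA_integer_, seed = seed)
}

#' Gene-set enrichment by resampling from an eligible pool
#'
#' Observed statistic: the fraction of target genes belonging to the
#' annotated set (e.g. genes with a cardiovascular knock-out phenotype).
#' The null draws |targets| genes without replacement from the eligible
#' pool (genes with at least one promoter-distal interaction),
#' \code{n_iter} times; fold, Z and one-sided p as in the fragment
#' enrichment machinery.
#'
#' @param target_genes character vector, subset of \code{eligible_pool}.
#' @param eligible_pool character vector of genes eligible as targets.
#' @param annotated_set character vector of annotated genes.
#' @param n_iter iterations (default 1000).
#' @param seed RNG seed.
#' @return EnrichmentResult list (observed, null_mean, null_sd, fold, z,
#'   p, iterations, seed).
#' @export
geneset_resample_enrichment <- function(target_genes, eligible_pool,
                                        annotated_set, n_iter = 1000L,
                                        seed = 1L) {
  target_genes <- unique(target_genes)
  eligible_pool <- unique(eligible_pool)
  if (!all(target_genes %in% eligible_pool))
    stopf("target genes must be a subset of the eligible pool")
  if (length(eligible_pool) < length(target_genes))
    stopf("eligible pool smaller than the target set")
  ann <- eligible_pool %in% annotated_set
  observed <- mean(target_genes %in% annotated_set)
  set.seed(seed)
  nulls <- vapply(seq_len(n_iter), function(i)
    mean(ann[sample.int(length(eligible_pool), length(target_genes))]),
    numeric(1))
  .enrichment_result(observed, nulls, n_iter, seed)
}

#' Hypergeometric GO-term enrichment with parent propagation
#'
#' Gene-term annotations are first propagated to every ancestor term of
#' the ontology graph, then each term with at least one hit in the gene
#' set is tested with the upper-tail hypergeometric distribution (is the
#' term over-represented in the set relative to the universe?), and
#' p-values are Benjamini-Hochberg adjusted across the tested terms.
#'
#' @param gene_set character vector, subset of \code{universe}.
#' @param universe character vector of all eligible genes.
#' @param dag ontology as from [read_obo_lite()].
#' @param associations data.table gene, term (direct annotations).
#' @return data.table: term, name, universe_n, term_universe, set_n,
#'   term_set, p, q — sorted by p.
#' @export
go_enrichment <- function(gene_set, universe, dag, associations) {
  universe <- unique(universe)
  gene_set <- unique(gene_set)
  if (!length(universe)) stopf("empty universe")
  if (!all(gene_set %in% universe))
    stopf("gene_set must be a subset of the universe")
  assoc <- as.data.table(associations)[gene %in% universe]
  anc <- obo_ancestors(dag)
  known <- assoc$term %in% names(anc)
  if (!all(known))
    stopf("associations reference unknown term(s): %s",
          paste(unique(assoc$term[!known]), collapse = ", "))
  prop <- assoc[, .(term = unique(c(term, unlist(anc[term],
                                                 use.names = FALSE)))),
                by = gene]
  term_univ <- prop[, .(term_universe = uniqueN(gene)), by = term]
  in_set <- prop[gene %in% gene_set,
                 .(term_set = uniqueN(gene)), by = term]
  res <- term_univ[in_set, on = "term"]
  if (!nrow(res))
    return(data.table(term = character(), name = character(),
                      universe_n = integer(), term_universe = integer(),
                      set_n = integer(), term_set = integer(),
                      p = numeric(), q = numeric()))
  N <- length(universe); n <- length(gene_set)
  res[, `:=`(universe_n = N, set_n = n)]
  res[, p := phyper(term_set - 1, term_universe, N - term_universe, n,
                    lower.tail = FALSE)]
  res[, q := bh_adjust(p)]
  nm <- as.data.table(dag$terms)
  res <- nm[, .(term = id, name)][res, on = "term"]
  setorder(res, p)
  res[, .(term, name, universe_n, term_universe, set_n, term_set, p, q)]
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Validated wrapper over \code{stats::p.adjust(method = "BH")}.
#' @param p_values numeric vector of p-values in [0,1].
#' @return adjusted q-values.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stopf("p-values must lie in [0,1]")
  p.adjust(p_values, method = "BH")
}
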