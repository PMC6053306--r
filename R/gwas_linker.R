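# LD expansion of GWAS tag SNPs over a phased haplotype panel and linkage
# of LD SNPs to target genes through consensus promoter interactions.

#' Pairwise linkage disequilibrium r-squared between two variants
#'
#' Computed from phased 0/1 haplotype vectors as r² = D² / (pA pa pB pb)
#' with D = pAB − pA·pB. Equivalent to the squared Pearson correlation of
#' the two allele-indicator vectors. Symmetric and invariant to allele
#' label swaps.
#'
#' @param alleles_a,alleles_b equal-length 0/1 vectors (one entry per
#'   haplotype).
#' @return r² in [0,1]; NA when either variant is monomorphic.
#' @export
r_squared <- function(alleles_a, alleles_b) {
  if (length(alleles_a) != length(alleles_b))
    stopf("haplotype vectors differ in length")
  if (!all(alleles_a %in% 0:1) || !all(alleles_b %in% 0:1))
    stopf("alleles must be coded 0/1")
  pa <- mean(alleles_a); pb <- mean(alleles_b)
  if (pa %in% c(0, 1) || pb %in% c(0, 1)) return(NA_real_)
  d <- mean(alleles_a * alleles_b) - pa * pb
  d^2 / (pa * (1 - pa) * pb * (1 - pb))
}

#' Minor allele frequency from a 0/1 haplotype vector
#' @param alleles 0/1 vector.
#' @return MAF in [0, 0.5].
#' @export
minor_allele_freq <- function(alleles) {
  p <- mean(alleles)
  min(p, 1 - p)
}

#' Expand tag SNPs to all SNPs in high LD
#'
#' For each tag SNP, considers every panel variant within \code{window} bp
#' (a 2×window interval centered on the tag), retains those with
#' r² > \code{r2_min} to the tag and MAF >= \code{maf_min}; the tag itself
#' is always retained (r² = 1). Across tags of one disease class, each SNP
#' is kept once with its highest r².
#'
#' @param tag_snps data.table snp, chrom, pos, disease_class.
#' @param panel haplotype panel ([read_haplotype_panel()]).
#' @param window half-width in bp (default 5e4).
#' @param r2_min r² threshold, exclusive (default 0.9).
#' @param maf_min MAF threshold, inclusive (default 0.01).
#' @return data.table snp, chrom, pos, r2, maf, tag_snp, disease_class.
#' @export
ld_expand <- function(tag_snps, panel, window = 5e4, r2_min = 0.9,
                      maf_min = 0.01) {
  tags <- as.data.table(tag_snps)
  meta <- panel$meta; geno <- panel$geno
  out <- vector("list", nrow(tags))
  for (i in seq_len(nrow(tags))) {
    tid <- tags$snp[i]
    j <- match(tid, meta$snp)
    if (is.na(j)) {
      warnf("tag SNP %s absent from panel; skipped", tid)
      next
    }
    tvec <- geno[j, ]
    cand <- which(meta$chrom == meta$chrom[j] &
                    abs(meta$pos - meta$pos[j]) <= window)
    rows <- lapply(cand, function(k) {
      if (k == j) return(data.table(
        snp = tid, chrom = meta$chrom[k], pos = meta$pos[k], r2 = 1,
        maf = minor_allele_freq(geno[k, ])))
      r2v <- r_squared(tvec, geno[k, ])
      mafv <- minor_allele_freq(geno[k, ])
      if (is.na(r2v) || r2v <= r2_min || mafv < maf_min) return(NULL)
      data.table(snp = meta$snp[k], chrom = meta$chrom[k],
                 pos = meta$pos[k], r2 = r2v, maf = mafv)
    })
    res <- rbindlist(Filter(Negate(is.null), rows))
    if (nrow(res)) {
      res[, `:=`(tag_snp = tid, disease_class = tags$disease_class[i])]
      out[[i]] <- res
    }
  }
  all <- rbindlist(Filter(Negate(is.null), out))
  if (!nrow(all))
    return(data.table(snp = character(), chrom = character(),
                      pos = numeric(), r2 = numeric(), maf = numeric(),
                      tag_snp = character(), disease_class = character()))
  # one record per SNP per disease class, keeping the highest r2
  setorder(all, disease_class, snp, -r2)
  unique(all, by = c("disease_class", "snp"))
}

#' Link LD SNPs to target genes through promoter interactions
#'
#' SNPs residing inside any captured promoter region are excluded first
#' ("non-promoter SNPs"); a link exists when the SNP position falls inside
#' the \code{ext}-extended distal interval of a consensus interaction; one
#' link per (SNP, gene) pair.
#'
#' @param ld_snps LD SNP table ([ld_expand()]).
#' @param consensus consensus interaction table.
#' @param promoter_regions promoter region table.
#' @param ext extension in bp (default 1000; SNP linking uses 1 kb-extended
#'   interactions).
#' @return data.table snp, chrom, pos, disease_class, target_gene,
#'   prom_start, prom_end, dist_bp (|SNP − promoter midpoint|).
#' @export
link_snps <- function(ld_snps, consensus, promoter_regions, ext = 1000) {
  snps <- as.data.table(ld_snps)
  pr <- as.data.table(promoter_regions)
  cons <- as.data.table(consensus)
  if (!nrow(snps))
    return(data.table(snp = character(), chrom = character(),
                      pos = numeric(), disease_class = character(),
                      target_gene = character(), prom_start = numeric(),
                      prom_end = numeric(), dist_bp = numeric()))
  # drop SNPs inside any captured promoter region
  in_prom <- vapply(seq_len(nrow(snps)), function(i)
    pr[chrom == snps$chrom[i] & start <= snps$pos[i] & snps$pos[i] < end,
       .N] > 0, logical(1))
  snps <- snps[!in_prom]
  if (!nrow(snps) || !nrow(cons))
    return(data.table(snp = character(), chrom = character(),
                      pos = numeric(), disease_class = character(),
                      target_gene = character(), prom_start = numeric(),
                      prom_end = numeric(), dist_bp = numeric()))
  ci <- cons[, .(gene, chrom, start = other_start - ext,
                 end = other_end + ext, prom_start = bait_start,
                 prom_end = bait_end)]
  setkey(ci, chrom, start, end)
  sq <- snps[, .(chrom, start = pos, end = pos + 1,
                 xid = seq_len(nrow(snps)))]
  hits <- foverlaps(sq, ci, by.x = c("chrom", "start", "end"),
                    type = "any", nomatch = NULL)
  hits <- hits[i.start >= start & i.start < end]
  if (!nrow(hits))
    return(data.table(snp = character(), chrom = character(),
                      pos = numeric(), disease_class = character(),
                      target_gene = character(), prom_start = numeric(),
                      prom_end = numeric(), dist_bp = numeric()))
  links <- hits[, .(
    snp = snps$snp[xid], chrom, pos = snps$pos[xid],
    disease_class = snps$disease_class[xid], target_gene = gene,
    prom_start, prom_end)]
  links <- unique(links, by = c("snp", "target_gene"))
  links[, dist_bp := abs(pos - midpoint(prom_start, prom_end))]
  links[]
}

#' Number of gene promoters skipped by a SNP-target link
#'
#' Counts distinct genes (other than the target) with at least one TSS
#' strictly between the SNP position and the edge of the target promoter
#' region nearest the SNP.
#'
#' @param links link table ([link_snps()]).
#' @param tss_catalog full TSS catalog.
#' @return integer vector, one count per link.
#' @export
skip_count <- function(links, tss_catalog) {
  lk <- as.data.table(links)
  tss <- as.data.table(tss_catalog)
  vapply(seq_len(nrow(lk)), function(i) {
    s <- lk$pos[i]
    edge <- if (s < lk$prom_start[i]) lk$prom_start[i] else lk$prom_end[i]
    lo <- min(s, edge); hi <- max(s, edge)
    tss[chrom == lk$chrom[i] & pos > lo & pos < hi &
          gene != lk$target_gene[i], uniqueN(gene)]
  }, integer(1))
}

#' Summary statistics of SNP-target gene links
#'
#' @param links link table with dist_bp (and optionally n_skipped).
#' @param domains optional domain table for the same-TAD fraction.
#' @param tss_catalog optional TSS catalog to compute skip counts when the
#'   links table lacks them.
#' @return list: n_snps, n_genes, median_dist, mean_dist, pct_same_tad,
#'   genes_per_snp (table), skip_counts (table), pct_skipping (fraction of
#'   links skipping >= 1 promoter, as a percentage).
#' @export
link_summary <- function(links, domains = NULL, tss_catalog = NULL) {
  lk <- as.data.table(links)
  if (!nrow(lk))
    return(list(n_snps = NA, n_genes = NA, median_dist = NA,
                mean_dist = NA, pct_same_tad = NA, genes_per_snp = NA,
                skip_counts = NA, pct_skipping = NA))
  if (!"n_skipped" %in% names(lk)) {
    if (is.null(tss_catalog)) lk[, n_skipped := NA_integer_]
    else lk[, n_skipped := skip_count(lk, tss_catalog)]
  }
  same_tad <- NA_real_
  if (!is.null(domains)) {
    dom <- as.data.table(domains)
    if ("label" %in% names(dom)) dom <- dom[label == "domain"]
    st <- vapply(seq_len(nrow(lk)), function(i) {
      pm <- midpoint(lk$prom_start[i], lk$prom_end[i])
      d <- dom[chrom == lk$chrom[i]]
      any(d$start <= lk$pos[i] & lk$pos[i] < d$end &
            d$start <= pm & pm < d$end)
    }, logical(1))
    lk[, same_tad := st]
    same_tad <- 100 * mean(st)
  }
  gps <- lk[, .(n = uniqueN(target_gene)), by = snp]
  list(
    n_snps = uniqueN(lk$snp),
    n_genes = uniqueN(lk$target_gene),
    median_dist = median(lk$dist_bp),
    mean_dist = mean(lk$dist_bp),
    pct_same_tad = same_tad,
    genes_per_snp = table(gps$n),
    skip_counts = table(lk$n_skipped),
    pct_skipping = if (all(is.na(lk$n_skipped))) NA_real_
                   else 100 * mean(lk$n_skipped >= 1, na.rm = TRUE)
  )
}
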