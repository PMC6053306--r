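# Randomized restriction-fragment background enrichment for chromatin
# features, expression-binned enrichment, the cell-type specificity grid
# and the peak-density/expression correlation.

#' Fragments eligible as random background
#'
#' Removes from the fragment map every fragment overlapping an excluded
#' region (captured promoter regions, unmappable gaps).
#'
#' @param fragment_map fragment map table.
#' @param exclude_regions data.table chrom, start, end (may be empty).
#' @return data.table of eligible fragments.
#' @export
background_pool <- function(fragment_map, exclude_regions = NULL) {
  fm <- as.data.table(fragment_map)
  if (is.null(exclude_regions) || !nrow(as.data.table(exclude_regions)))
    return(copy(fm))
  ex <- as.data.table(exclude_regions)[, .(chrom, start, end)]
  setkey(ex, chrom, start, end)
  q <- fm[, .(chrom, start, end, frag_id)]
  hits <- foverlaps(q, ex, by.x = c("chrom", "start", "end"),
                    type = "any", nomatch = NULL)
  drop <- hits[i.start < end & start < i.end, unique(frag_id)]
  fm[!frag_id %in% drop]
}

#' Sample background fragments for the enrichment null
#'
#' Uniform sampling of \code{n} fragments without replacement within each
#' iteration, from the eligible pool; reproducible given \code{seed}.
#'
#' @param pool eligible fragment table ([background_pool()]).
#' @param n fragments per iteration.
#' @param iterations number of iterations (default 100).
#' @param seed RNG seed (recorded in downstream results).
#' @return list of length \code{iterations}, each an integer vector of
#'   fragment ids.
#' @export
sample_background_fragments <- function(pool, n, iterations = 100L,
                                        seed = 1L) {
  pool <- as.data.table(pool)
  if (nrow(pool) < n)
    stopf("background pool (%d) smaller than requested n (%d)",
          nrow(pool), n)
  set.seed(seed)
  lapply(seq_len(iterations),
         function(i) sample(pool$frag_id, n, replace = FALSE))
}

# fraction of fragments (given as a table chrom/start/end) overlapping >= 1
# peak by >= 1 bp
.overlap_fraction <- function(frags, peaks) {
  if (!nrow(frags)) return(NA_real_)
  if (!nrow(peaks)) return(0)
  pk <- as.data.table(peaks)[, .(chrom, start, end)]
  setkey(pk, chrom, start, end)
  q <- copy(as.data.table(frags))[, xid := seq_len(.N)]
  hits <- foverlaps(q[, .(chrom, start, end, xid)], pk,
                    by.x = c("chrom", "start", "end"),
                    type = "any", nomatch = NULL)
  length(hits[i.start < end & start < i.end, unique(xid)]) / nrow(q)
}

.enrichment_result <- function(observed, null_props, iterations, seed) {
  mu <- mean(null_props); s <- sd(null_props)
  z <- if (is.na(s) || s == 0) NA_real_ else (observed - mu) / s
  p <- if (is.na(z)) { warnf("null sd is zero; p undefined"); NA_real_ }
       else pnorm(abs(z), lower.tail = FALSE)
  list(observed = observed, null_mean = mu, null_sd = s,
       fold = if (mu > 0) observed / mu else NA_real_,
       z = z, p = p, iterations = iterations, seed = seed)
}

#' Fold enrichment of interacting fragments over random fragments
#'
#' Compares the observed proportion of distinct promoter-interacting
#' fragments overlapping a feature to the proportion among randomly drawn
#' background fragments (matched in number), over \code{iterations}
#' iterations. Fold = observed / null mean; Z = (observed - null mean) /
#' null sd; one-sided normal-tail p in the direction of the observed
#' deviation.
#'
#' @param distal_fragments data.table chrom, start, end, frag_id of the
#'   distinct promoter-distal interacting fragments (fragment-level, not
#'   extended).
#' @param feature_peaks peak BED table (promoter-distal peaks).
#' @param pool background pool ([background_pool()]).
#' @param iterations background iterations (default 100).
#' @param seed RNG seed.
#' @return EnrichmentResult list: observed, null_mean, null_sd, fold, z, p,
#'   iterations, seed.
#' @export
enrichment <- function(distal_fragments, feature_peaks, pool,
                       iterations = 100L, seed = 1L) {
  df <- unique(as.data.table(distal_fragments), by = "frag_id")
  pool <- as.data.table(pool)
  observed <- .overlap_fraction(df, feature_peaks)
  # per-fragment overlap flag over the pool, computed once
  pk <- as.data.table(feature_peaks)
  if (nrow(pk)) {
    pk <- pk[, .(chrom, start, end)]
    setkey(pk, chrom, start, end)
    qq <- pool[, .(chrom, start, end, frag_id)]
    h <- foverlaps(qq, pk, by.x = c("chrom", "start", "end"),
                   type = "any", nomatch = NULL)
    hit_ids <- h[i.start < end & start < i.end, unique(frag_id)]
  } else hit_ids <- integer(0)
  flag <- pool$frag_id %in% hit_ids
  draws <- sample_background_fragments(pool, nrow(df), iterations, seed)
  null_props <- vapply(draws, function(ids)
    mean(flag[match(ids, pool$frag_id)]), numeric(1))
  .enrichment_result(observed, null_props, iterations, seed)
}

#' Assign genes to TPM expression bins
#'
#' Bins partition [0, Inf): bin 1 = exactly 0 TPM, bin 2 = (0,3], bin 3 =
#' (3,25], bin 4 = (25,150], bin 5 = (150,Inf) — right-closed boundaries.
#'
#' @param tpm numeric vector of average TPM values.
#' @return integer vector of bin indices 1..5.
#' @export
expression_bin <- function(tpm) {
  if (any(tpm < 0, na.rm = TRUE)) stopf("TPM values must be >= 0")
  ifelse(tpm == 0, 1L,
         as.integer(cut(tpm, c(0, 3, 25, 150, Inf), right = TRUE)) + 1L)
}

#' Enrichment per expression bin
#'
#' Genes are grouped into five bins by average TPM; the fragment-overlap
#' enrichment is run per bin on that bin's distinct distal fragments.
#'
#' @param tpm_table data.table gene, tpm (average over replicates).
#' @param consensus consensus interactions with a frag-level distal end and
#'   other_frag_id column (or distal coordinates resolvable via
#'   \code{fragment_map}).
#' @param feature_peaks peak table.
#' @param pool background pool.
#' @param fragment_map fragment map, used to resolve distal fragment ids.
#' @param iterations,seed as in [enrichment()].
#' @return data.table with one EnrichmentResult row per non-empty bin.
#' @export
binned_enrichment <- function(tpm_table, consensus, feature_peaks, pool,
                              fragment_map, iterations = 100L, seed = 1L) {
  tp <- as.data.table(tpm_table)
  cons <- as.data.table(consensus)
  cons <- tp[cons, on = "gene", nomatch = NULL]
  cons[, bin := expression_bin(tpm)]
  res <- vector("list", 5L)
  for (b in 1:5) {
    sub <- cons[bin == b]
    if (!nrow(sub)) { warnf("expression bin %d is empty; skipped", b); next }
    fb <- distal_fragment_table(sub, fragment_map)
    if (!nrow(fb)) { warnf("expression bin %d is empty; skipped", b); next }
    r <- enrichment(fb, feature_peaks, pool, iterations, seed + b)
    res[[b]] <- c(list(bin = b, n_fragments = nrow(fb)), r)
  }
  rbindlist(Filter(Negate(is.null), res))
}

#' Distinct distal fragments of a set of interactions
#'
#' Resolves each interaction's distal interval to the restriction fragments
#' it covers (>= 1 bp overlap) and returns the distinct fragment records.
#'
#' @param interactions table with other_chrom/other_start/other_end (and
#'   chrom fallback).
#' @param fragment_map fragment map.
#' @return data.table chrom, start, end, frag_id (distinct fragments).
#' @export
distal_fragment_table <- function(interactions, fragment_map) {
  x <- as.data.table(interactions)
  fm <- copy(as.data.table(fragment_map))
  ochr <- if ("other_chrom" %in% names(x)) x$other_chrom else x$chrom
  q <- data.table(chrom = ochr, start = x$other_start, end = x$other_end)
  setkey(fm, chrom, start, end)
  hits <- foverlaps(q[, xid := seq_len(.N)], fm,
                    by.x = c("chrom", "start", "end"),
                    type = "any", nomatch = NULL)
  real <- hits[i.start < end & start < i.end]
  unique(real[, .(chrom, start, end, frag_id)], by = "frag_id")
}

#' Cell-type specificity enrichment grid
#'
#' Cross-tabulates interaction classes (A-specific, B-specific, shared;
#' columns) against feature classes (A-only, B-only, shared; rows): one
#' independent enrichment run per cell, each with its own matched
#' background. A peak is "shared" when it overlaps (>= 1 bp) any peak of
#' the other cell type, else cell-type-specific.
#'
#' @param interaction_sets named list of three interaction tables
#'   (A_specific, B_specific, shared), each resolvable to distal fragments.
#' @param peaks_a,peaks_b peak tables of the two cell types.
#' @param pool background pool.
#' @param fragment_map fragment map.
#' @param iterations,seed as in [enrichment()].
#' @return data.table: interaction_class, feature_class, plus
#'   EnrichmentResult columns.
#' @export
specificity_matrix <- function(interaction_sets, peaks_a, peaks_b, pool,
                               fragment_map, iterations = 100L, seed = 1L) {
  stopifnot(all(c("A_specific", "B_specific", "shared") %in%
                  names(interaction_sets)))
  fclasses <- partition_peaks(peaks_a, peaks_b)
  out <- list()
  k <- 0L
  for (ic in names(interaction_sets)) {
    ft <- distal_fragment_table(interaction_sets[[ic]], fragment_map)
    for (fc in names(fclasses)) {
      k <- k + 1L
      if (!nrow(fclasses[[fc]])) next
      r <- enrichment(ft, fclasses[[fc]], pool, iterations, seed + k)
      out[[length(out) + 1L]] <-
        c(list(interaction_class = ic, feature_class = fc), r)
    }
  }
  rbindlist(out)
}

#' Partition two peak sets into A-only, B-only and shared classes
#' @param peaks_a,peaks_b peak tables (chrom, start, end).
#' @return named list A_only, B_only, shared (shared = peaks of either cell
#'   type overlapping the other; reported on A coordinates plus B-side
#'   unmatched duplicates removed).
#' @export
partition_peaks <- function(peaks_a, peaks_b) {
  a <- as.data.table(peaks_a)[, .(chrom, start, end)]
  b <- as.data.table(peaks_b)[, .(chrom, start, end)]
  ov <- function(x, y) {
    if (!nrow(x) || !nrow(y)) return(logical(nrow(x)))
    yk <- copy(y); setkey(yk, chrom, start, end)
    xq <- copy(x)[, xid := seq_len(.N)]
    h <- foverlaps(xq, yk, by.x = c("chrom", "start", "end"),
                   type = "any", nomatch = NULL)
    seq_len(nrow(x)) %in% h[i.start < end & start < i.end, unique(xid)]
  }
  a_shared <- ov(a, b); b_shared <- ov(b, a)
  list(A_only = a[!a_shared], B_only = b[!b_shared],
       shared = a[a_shared])
}

#' Spearman correlation of expression with local peak density
#'
#' Counts the feature peaks whose midpoint lies within \code{window} bp of
#' each gene's TSS and correlates the count with the gene's average TPM
#' (Spearman, average ranks on ties, two-sided p). Restricted to genes with
#' at least one significant interaction when \code{genes_with_interactions}
#' is supplied.
#'
#' @param tpm_table data.table gene, tpm.
#' @param peaks peak table.
#' @param tss_catalog TSS catalog.
#' @param window half-width in bp (default 3e5).
#' @param genes_with_interactions optional character vector filter.
#' @return list(rho, p, n).
#' @export
peak_density_expression_corr <- function(tpm_table, peaks, tss_catalog,
                                         window = 3e5,
                                         genes_with_interactions = NULL) {
  tp <- as.data.table(tpm_table)
  tss <- as.data.table(tss_catalog)
  if (!is.null(genes_with_interactions))
    tp <- tp[gene %in% genes_with_interactions]
  d <- tss[tp, on = "gene", nomatch = NULL]
  if (nrow(d) < 3) stopf("need >= 3 genes after filtering")
  pk <- as.data.table(peaks)
  pk[, mid := midpoint(start, end)]
  cnt <- vapply(seq_len(nrow(d)), function(i)
    pk[chrom == d$chrom[i] & abs(mid - d$pos[i]) <= window, .N],
    numeric(1))
  if (length(unique(cnt)) < 2 || length(unique(d$tpm)) < 2) {
    warnf("constant vector; Spearman correlation undefined")
    return(list(rho = NA_real_, p = NA_real_, n = nrow(d)))
  }
  ct <- suppressWarnings(
    cor.test(d$tpm, cnt, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = nrow(d))
}
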