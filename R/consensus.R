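# Interaction-calling post-processing: promoter-level summarisation,
# minimum-distance filter, replicate consensus with 1 kb-extension
# matching, cell-type specificity, categorisation and distance summaries.

#' Summarise fragment-level interactions at the merged-TSS promoter level
#'
#' Replaces each record's bait interval with the promoter region of its
#' gene; records for genes without a promoter region are dropped with a
#' warning; trans records are dropped.
#'
#' @param interactions internal interaction table (see
#'   [read_interactions()]).
#' @param promoter_regions as from [merge_promoter_regions()].
#' @return interaction table with bait coordinates replaced by promoter
#'   region coordinates.
#' @export
summarise_by_promoter <- function(interactions, promoter_regions) {
  x <- as.data.table(interactions)
  pr <- as.data.table(promoter_regions)
  if ("is_trans" %in% names(x)) {
    x <- x[is_trans == FALSE | is.na(is_trans)]
  }
  miss <- setdiff(unique(x$gene), pr$gene)
  if (length(miss))
    warnf("dropping %d record(s) for %d gene(s) without a promoter region",
          nrow(x[gene %in% miss]), length(miss))
  x <- x[gene %in% pr$gene]
  x[pr, on = "gene", `:=`(bait_start = i.start, bait_end = i.end)]
  x[]
}

#' Span distance of an interaction
#'
#' Distance between the midpoint of the promoter (bait) interval and the
#' midpoint of the distal interval, in bp.
#' @param interactions internal interaction table.
#' @return numeric vector of distances.
#' @export
span_distance <- function(interactions) {
  x <- as.data.table(interactions)
  abs(midpoint(x$bait_start, x$bait_end) -
        midpoint(x$other_start, x$other_end))
}

#' Filter interactions by minimum span distance
#'
#' Retains interactions whose span distance is at least \code{min_bp}
#' (boundary inclusive). Close-proximity ligation products below ~10 kb are
#' dominated by random Brownian contacts and are removed before any
#' downstream analysis.
#'
#' @param interactions internal interaction table (cis records).
#' @param min_bp minimum span distance in bp (default 10000).
#' @return filtered data.table with a dist_bp column.
#' @export
filter_min_distance <- function(interactions, min_bp = 10000) {
  x <- as.data.table(interactions)
  if ("is_trans" %in% names(x) && any(x$is_trans, na.rm = TRUE))
    stopf("filter_min_distance expects cis records only")
  x[, dist_bp := span_distance(x)]
  x[dist_bp >= min_bp]
}

# cluster 1 kb-extended intervals by transitive overlap within one gene;
# returns an integer cluster id per row (rows sorted arbitrarily)
.cluster_extended <- function(s, e, ext) {
  es <- s - ext; ee <- e + ext
  o <- order(es, ee)
  cl <- integer(length(s))
  cur <- 0L; cmax <- -Inf
  for (i in o) {
    if (es[i] >= cmax) { cur <- cur + 1L; cmax <- ee[i] }
    else cmax <- max(cmax, ee[i])
    cl[i] <- cur
  }
  cl
}

#' Replicate consensus of promoter interactions
#'
#' Two replicate records match when they concern the same gene and their
#' distal intervals, extended by \code{ext} bp on each side, overlap by at
#' least 1 bp. Matching is transitive-closure clustering within a gene;
#' clusters supported by at least \code{min_support} distinct replicates
#' are emitted. The emitted distal interval is the union envelope of the
#' member fragments (un-extended); the reported score is the per-replicate
#' maximum.
#'
#' @param per_replicate named list of interaction tables, one per
#'   replicate, already promoter-summarised and distance-filtered.
#' @param ext extension in bp applied to each side of the distal interval
#'   (default 1000).
#' @param min_support minimum number of distinct supporting replicates
#'   (default 2).
#' @return data.table: gene, chrom, bait_start, bait_end, other_start,
#'   other_end, support, replicates (comma-joined labels), score (max),
#'   dist_bp.
#' @export
replicate_consensus <- function(per_replicate, ext = 1000, min_support = 2L) {
  if (length(per_replicate) < 2)
    stopf("replicate consensus needs >= 2 replicates")
  labs <- names(per_replicate) %||% as.character(seq_along(per_replicate))
  if (is.null(names(per_replicate))) names(per_replicate) <- labs
  all <- rbindlist(lapply(labs, function(l) {
    d <- as.data.table(per_replicate[[l]])
    d[, replicate := l]
    d
  }), use.names = TRUE, fill = TRUE)
  if (!nrow(all))
    return(data.table(gene = character(), chrom = character(),
                      bait_start = numeric(), bait_end = numeric(),
                      other_start = numeric(), other_end = numeric(),
                      support = integer(), replicates = character(),
                      score = numeric(), dist_bp = numeric()))
  all[, cluster := .cluster_extended(other_start, other_end, ext),
      by = gene]
  cons <- all[, .(
    chrom = bait_chrom[1],
    bait_start = bait_start[1], bait_end = bait_end[1],
    other_start = min(other_start), other_end = max(other_end),
    support = uniqueN(replicate),
    replicates = paste(sort(unique(replicate)), collapse = ","),
    score = max(score, na.rm = TRUE)
  ), by = .(gene, cluster)]
  cons <- cons[support >= min_support][, cluster := NULL]
  cons[, dist_bp := abs(midpoint(bait_start, bait_end) -
                          midpoint(other_start, other_end))]
  setorder(cons, chrom, gene, other_start)
  cons[]
}

#' Split a consensus set into cell-type-specific and shared interactions
#'
#' A consensus interaction of cell type A is A-specific when no record for
#' the same gene in any replicate of cell type B overlaps it under the same
#' extension rule (extended-vs-extended, >= 1 bp); presence in a single B
#' replicate — even below the consensus support threshold — makes it
#' shared.
#'
#' @param consensus_a consensus table of cell type A
#'   ([replicate_consensus()]).
#' @param replicates_b list of per-replicate interaction tables of cell
#'   type B (promoter-summarised, distance-filtered).
#' @param ext extension in bp (default 1000).
#' @return \code{consensus_a} with a specificity column
#'   ("specific"/"shared").
#' @export
cell_type_specific <- function(consensus_a, replicates_b, ext = 1000) {
  a <- copy(as.data.table(consensus_a))
  b <- rbindlist(lapply(replicates_b, as.data.table),
                 use.names = TRUE, fill = TRUE)
  if (!nrow(a)) { a[, specificity := character(0)]; return(a[]) }
  if (!nrow(b)) { a[, specificity := "specific"]; return(a[]) }
  bq <- b[, .(gene, start = other_start - ext, end = other_end + ext)]
  setkey(bq, gene, start, end)
  aq <- a[, .(gene, start = other_start - ext, end = other_end + ext,
              xid = seq_len(nrow(a)))]
  hits <- foverlaps(aq, bq, by.x = c("gene", "start", "end"),
                    type = "any", nomatch = NULL)
  # foverlaps closed-interval semantics admit zero-width touching; require
  # a true >= 1 bp half-open overlap
  real <- hits[i.start < end & start < i.end, unique(xid)]
  a[, specificity := "specific"]
  if (length(real)) a[real, specificity := "shared"]
  a[]
}

#' Categorise interactions by the nature of their distal end
#'
#' P-promoter: the distal interval contains a TSS of a captured gene;
#' P-proximal: the distal interval overlaps the captured (bait) region but
#' no TSS; P-distal: the distal interval is outside the captured region.
#'
#' @param interactions consensus or per-replicate table.
#' @param bait_fragments data.table chrom, start, end of all bait fragments
#'   (the captured region).
#' @param tss_catalog TSS catalog restricted to captured genes.
#' @return character vector of categories, parallel to the rows.
#' @export
categorize_interaction <- function(interactions, bait_fragments,
                                   tss_catalog) {
  x <- as.data.table(interactions)
  if (!nrow(x)) return(character(0))
  tss <- as.data.table(tss_catalog)
  bf <- as.data.table(bait_fragments)
  cat <- rep("P-distal", nrow(x))
  ochr <- if ("other_chrom" %in% names(x)) x$other_chrom else x$chrom
  # overlap with captured region
  bq <- bf[, .(chrom, start, end)]
  setkey(bq, chrom, start, end)
  aq <- data.table(chrom = ochr, start = x$other_start, end = x$other_end,
                   xid = seq_len(nrow(x)))
  hits <- foverlaps(aq, bq, by.x = c("chrom", "start", "end"),
                    type = "any", nomatch = NULL)
  prox <- hits[i.start < end & start < i.end, unique(xid)]
  cat[prox] <- "P-proximal"
  # contains a captured TSS (position in half-open interval)
  tq <- tss[, .(chrom, start = pos, end = pos + 1)]
  setkey(tq, chrom, start, end)
  hits2 <- foverlaps(aq, tq, by.x = c("chrom", "start", "end"),
                     type = "any", nomatch = NULL)
  prom <- hits2[start >= i.start & start < i.end, unique(xid)]
  cat[prom] <- "P-promoter"
  cat
}

#' Median and mean of interaction span distances
#' @param interactions table with a dist_bp column (or computable ends).
#' @return list(median, mean) in bp.
#' @export
distance_summary <- function(interactions) {
  x <- as.data.table(interactions)
  if (!nrow(x)) stopf("distance_summary: empty input")
  d <- if ("dist_bp" %in% names(x)) x$dist_bp else span_distance(x)
  list(median = median(d), mean = mean(d))
}
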