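# Coordinate scaffold: restriction-fragment maps, TSS catalog, bait
# selection and merged promoter regions. All coordinates are 0-based,
# half-open [start, end); 1-based inputs are converted at the I/O boundary.

#' Build a restriction-fragment map from cut positions
#'
#' Fragments tile each chromosome exactly: the first fragment starts at 0,
#' the last ends at the chromosome length, and adjacent fragments abut.
#' Fragment ids are globally unique integers, strictly increasing with
#' coordinate within each chromosome.
#'
#' @param layout named numeric vector of chromosome lengths (bp).
#' @param cut_positions named list (one element per chromosome) of strictly
#'   increasing cut positions, each strictly inside the chromosome. A
#'   chromosome absent from the list (or with an empty vector) yields a
#'   single fragment spanning the whole chromosome.
#' @return data.table with columns chrom, start, end, frag_id, keyed by
#'   chrom/start.
#' @export
build_fragment_map <- function(layout, cut_positions = list()) {
  layout <- validate_layout(layout)
  frags <- lapply(names(layout), function(chr) {
    len <- layout[[chr]]
    cuts <- as.numeric(cut_positions[[chr]] %||% numeric(0))
    if (length(cuts)) {
      if (is.unsorted(cuts, strictly = TRUE))
        stopf("cut positions on %s are not strictly increasing", chr)
      if (cuts[1] <= 0 || cuts[length(cuts)] >= len)
        stopf("cut positions on %s fall outside (0, %d)", chr, as.integer(len))
    }
    bounds <- c(0, cuts, len)
    data.table(chrom = chr, start = bounds[-length(bounds)], end = bounds[-1])
  })
  fm <- rbindlist(frags)
  fm[, frag_id := seq_len(.N)]
  setkey(fm, chrom, start)
  fm[]
}

#' Select bait fragments around transcription start sites
#'
#' Reproduces capture-probe fragment selection: restriction fragments longer
#' than \code{min_len} overlapping a \code{window} on each side of a TSS are
#' eligible; of TSSs closer than \code{dedup_dist} to each other only one is
#' retained (the smallest coordinate); per retained TSS the \code{n_ends}
#' fragment ends (cut-site boundaries) closest to the TSS are selected, each
#' fragment contributing at most one end before its second end is
#' considered. The bait set of a gene is the set of fragments owning the
#' selected ends.
#'
#' @param tss_catalog data.table with columns gene, chrom, pos, strand.
#' @param fragment_map as returned by [build_fragment_map()].
#' @param window half-width of the TSS window in bp (default 10000).
#' @param min_len minimum fragment length in bp, exclusive (default 200).
#' @param dedup_dist TSS deduplication distance in bp (default 1000).
#' @param n_ends number of fragment ends selected per TSS (default 4).
#' @return list with elements \code{baits} (data.table gene, frag_id),
#'   \code{probe_ends} (data.table gene, frag_id, end_pos, side) and
#'   \code{retained_tss} (the deduplicated TSS catalog).
#' @export
select_bait_fragments <- function(tss_catalog, fragment_map,
                                  window = 10000L, min_len = 200L,
                                  dedup_dist = 1000L, n_ends = 4L) {
  tss <- as.data.table(tss_catalog)
  req <- c("gene", "chrom", "pos", "strand")
  if (!all(req %in% names(tss)))
    stopf("tss_catalog must have columns %s", paste(req, collapse = ", "))
  if (!all(tss$strand %in% c("+", "-")))
    stopf("strand must be '+' or '-'")
  setorder(tss, chrom, pos)

  # greedy left-to-right dedup: keep a TSS only if >= dedup_dist from the
  # previously kept one on the same chromosome (keeps smallest coordinate)
  tss[, keep := {
    k <- logical(.N); last <- -Inf
    for (i in seq_len(.N)) {
      if (pos[i] - last >= dedup_dist) { k[i] <- TRUE; last <- pos[i] }
    }
    k
  }, by = chrom]
  kept <- tss[keep == TRUE][, keep := NULL]

  fm <- copy(as.data.table(fragment_map))
  setkey(fm, chrom, start, end)
  win <- kept[, .(gene, chrom, start = pos - window, end = pos + window,
                  pos)]
  cand <- foverlaps(win, fm, by.x = c("chrom", "start", "end"),
                    type = "any", nomatch = NULL)
  # half-open window overlap; fragment length strictly > min_len
  cand <- cand[i.start < end & start < i.end & end - start > min_len]
  no_frag <- setdiff(kept$gene, cand$gene)
  for (g in no_frag)
    warnf("no eligible bait fragment for gene %s", g)
  # both cut-site boundaries of each fragment are candidate probe ends
  ce <- rbind(
    cand[, .(gene, pos, frag_id, end_pos = start, side = "5p")],
    cand[, .(gene, pos, frag_id, end_pos = end,   side = "3p")]
  )
  ce[, dist_to_tss := abs(end_pos - pos)]
  setorder(ce, gene, dist_to_tss, end_pos)
  # pass 1: at most one end per fragment; pass 2: second ends if short
  pick <- function(fid) {
    first_mask <- !duplicated(fid)
    o <- c(which(first_mask), which(!first_mask))
    seq_along(fid) %in% o[seq_len(min(length(o), n_ends))]
  }
  probe_ends <- ce[, .SD[pick(frag_id)], by = gene,
                   .SDcols = c("frag_id", "end_pos", "side")]
  if (nrow(probe_ends)) {
    setcolorder(probe_ends, c("gene", "frag_id", "end_pos", "side"))
    baits <- unique(probe_ends[, .(gene, frag_id)])
  } else {
    probe_ends <- data.table(gene = character(), frag_id = integer(),
                             end_pos = numeric(), side = character())
    baits <- data.table(gene = character(), frag_id = integer())
  }
  setkey(baits, gene)
  list(baits = baits, probe_ends = probe_ends, retained_tss = kept)
}

#' Merge a gene's bait fragments into its promoter region
#'
#' The promoter region ("merged TSS") of a gene is the interval spanning all
#' of its bait fragments: from the smallest bait start to the largest bait
#' end. Genes annotated to identical bait fragments each receive their own
#' region record with identical coordinates.
#'
#' @param baits data.table (gene, frag_id) as from [select_bait_fragments()].
#' @param fragment_map fragment map supplying fragment coordinates.
#' @param tss_catalog TSS catalog supplying chrom and strand per gene.
#' @return data.table gene, chrom, start, end, strand — one row per gene.
#' @export
merge_promoter_regions <- function(baits, fragment_map, tss_catalog) {
  b <- as.data.table(baits)
  if (!nrow(b)) stopf("bait set is empty")
  fm <- as.data.table(fragment_map)
  coords <- fm[b, on = "frag_id"][, .(start = min(start), end = max(end),
                                      chrom = chrom[1]), by = gene]
  tssu <- unique(as.data.table(tss_catalog)[, .(gene, strand)], by = "gene")
  out <- tssu[coords, on = "gene"][, .(gene, chrom, start, end, strand)]
  setkey(out, gene)
  out[]
}

#' Map genomic positions to fragment ids
#'
#' @param fragment_map fragment map.
#' @param chroms,positions parallel vectors of query coordinates.
#' @return integer vector of fragment ids (NA where outside the map).
#' @export
locate_fragment <- function(fragment_map, chroms, positions) {
  fm <- as.data.table(fragment_map)
  q <- data.table(chrom = chroms, start = positions,
                  end = positions + 1, xid = seq_along(chroms))
  setkey(fm, chrom, start, end)
  hit <- foverlaps(q, fm, by.x = c("chrom", "start", "end"),
                   type = "within", nomatch = NA)
  hit[order(xid), frag_id]
}
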