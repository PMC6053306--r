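# Classification of interactions relative to topological domains and
# promoter-to-boundary distances. Domain calls (e.g. TopDom output) are
# consumed, never computed.

#' Read a domain-call BED with a label column
#'
#' Fourth column must be one of domain/boundary/gap (TopDom vocabulary).
#' Only rows labeled "domain" participate in classification.
#' @param path BED path.
#' @return data.table chrom, start, end, label.
#' @export
read_domains <- function(path) {
  dt <- read_bed(path)
  if (!"name" %in% names(dt)) stopf("%s: domain BED needs a label column", path)
  bad <- which(!dt$name %in% c("domain", "boundary", "gap"))
  if (length(bad))
    stopf("%s: unknown domain label '%s' at data line %d", path,
          dt$name[bad[1]], bad[1])
  dt[, .(chrom, start, end, label = name)]
}

#' Classify interactions as intra-TAD, inter-TAD or unassigned
#'
#' An interaction is \code{intra} when its entire span (from the leftmost
#' to the rightmost coordinate of both ends) is fully contained in a single
#' domain; \code{inter} when its two ends each overlap exactly one domain
#' and those domains differ; anything else (an end in a boundary or gap, or
#' an end straddling a domain edge) is \code{unassigned}.
#'
#' @param interactions consensus-style table (bait_* and other_* ends on
#'   column chrom).
#' @param domains data.table as from [read_domains()]; only rows labeled
#'   "domain" are used.
#' @return character vector: "intra", "inter" or "unassigned" per row.
#' @export
classify_tad <- function(interactions, domains) {
  x <- as.data.table(interactions)
  if (!nrow(x)) return(character(0))
  dom <- as.data.table(domains)
  if ("label" %in% names(dom)) dom <- dom[label == "domain"]
  n <- nrow(x)
  out <- rep("unassigned", n)
  doms_by_chr <- split(dom, dom$chrom)
  # ids of domains overlapping (>=1 bp) an interval; containment flag
  dom_hits <- function(chr, s, e) {
    d <- doms_by_chr[[chr]]
    if (is.null(d)) return(integer(0))
    which(d$start < e & s < d$end)
  }
  for (i in seq_len(n)) {
    chr <- x$chrom[i]
    d <- doms_by_chr[[chr]]
    if (is.null(d) || !nrow(d)) next
    span_s <- min(x$bait_start[i], x$other_start[i])
    span_e <- max(x$bait_end[i], x$other_end[i])
    contain <- which(d$start <= span_s & span_e <= d$end)
    if (length(contain)) { out[i] <- "intra"; next }
    h1 <- dom_hits(chr, x$bait_start[i], x$bait_end[i])
    h2 <- dom_hits(chr, x$other_start[i], x$other_end[i])
    if (length(h1) == 1 && length(h2) == 1 && h1 != h2) out[i] <- "inter"
  }
  out
}

#' Distance from a promoter midpoint to the nearest domain edge
#'
#' @param promoters data.table gene, chrom, start, end (promoter regions).
#' @param domains domain table; only rows labeled "domain" are used.
#' @return numeric vector of minimum |midpoint - edge| distances in bp; an
#'   error is raised for promoters on chromosomes without any domain.
#' @export
boundary_distance <- function(promoters, domains) {
  p <- as.data.table(promoters)
  dom <- as.data.table(domains)
  if ("label" %in% names(dom)) dom <- dom[label == "domain"]
  edges_by_chr <- lapply(split(dom, dom$chrom),
                         function(d) sort(c(d$start, d$end)))
  vapply(seq_len(nrow(p)), function(i) {
    ed <- edges_by_chr[[p$chrom[i]]]
    if (is.null(ed))
      stopf("no domains on chromosome %s", p$chrom[i])
    min(abs(midpoint(p$start[i], p$end[i]) - ed))
  }, numeric(1))
}
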