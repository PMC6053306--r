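#' @import data.table
#' @importFrom stats median p.adjust phyper pnorm rbinom rexp rgeom rnbinom
#'   rnorm rpois runif sd setNames cor.test wilcox.test quantile
#' @importFrom utils head tail
NULL

# quiet R CMD check notes for data.table NSE columns
utils::globalVariables(c(
  ".", ".N", ".SD", ".GRP", "..cols", "chrom", "start", "end", "frag_id",
  "gene", "pos", "strand", "tss", "score", "replicate", "bait_chrom",
  "bait_start", "bait_end", "other_chrom", "other_start", "other_end",
  "dist_bp", "support", "cluster", "ext_start", "ext_end", "mid", "value",
  "label", "category", "tad_class", "snp", "r2", "maf", "tag_snp",
  "disease_class", "target_gene", "same_tad", "n_skipped", "tpm", "bin",
  "term", "p", "q", "n_hits", "cell_type", "specificity", "i.start",
  "i.end", "i.gene", "i.strand", "loop_id", "true_gene", "name", "qflag",
  "eqtl_gene", "id", "parent", "N_reads", "keep", "dist_to_tss", "side",
  "len", "prom_start", "prom_end", "xid", "yid", "grp", "cmax", "rep_n",
  "obs", "compartment", "switch_class", "log2fc", "planted_gene",
  "cell_type", "anchor", "off", "width", "new_gene", "new_tss",
  "new_strand", "c1", "c2", "p_s", "p_e", "block", "center", "planted",
  "i.compartment", "is_trans", "N", "i.chrom", "end_pos", "ma", "mb",
  "term_set", "term_universe", "universe_n", "set_n", "bait_chr",
  "bait_name", "otherEnd_chr", "otherEnd_start", "otherEnd_end", "own"
))

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Validate a chromosome-length table
#'
#' @param layout named numeric vector, chromosome name -> length in bp.
#' @return the validated layout (invisibly re-typed to integer-valued double).
#' @keywords internal
validate_layout <- function(layout) {
  if (is.null(names(layout)) || anyDuplicated(names(layout)))
    stopf("genome layout must have unique chromosome names")
  if (any(!is.finite(layout)) || any(layout <= 0))
    stopf("chromosome lengths must be positive and finite")
  layout
}

# half-open interval overlap (>= 1 bp)
overlaps <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

midpoint <- function(s, e) (s + e) / 2
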