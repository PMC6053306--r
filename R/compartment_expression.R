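# A/B compartment assignment of genes, compartment-switch classification
# between cell types, and expression tests on switch classes.

#' Assign genes to A/B compartments by their TSS position
#'
#' The compartment track is either a signed bedGraph (value column;
#' positive = A under \code{positive_is} = "A") or a labeled BED (name
#' column in {A, B}). A TSS falling in no interval is "unassigned". The
#' eigenvector sign convention is supplied by the caller and never
#' inferred.
#'
#' @param tss_catalog TSS catalog.
#' @param track data.table chrom, start, end plus value (signed) or name
#'   (label).
#' @param positive_is which compartment a positive signal denotes ("A" or
#'   "B"; default "A").
#' @return data.table gene, compartment in {A, B, unassigned}.
#' @export
assign_compartment <- function(tss_catalog, track, positive_is = c("A", "B")) {
  positive_is <- match.arg(positive_is)
  tss <- as.data.table(tss_catalog)
  tr <- copy(as.data.table(track))
  if ("value" %in% names(tr)) {
    tr[, label := ifelse(value > 0, positive_is,
                         setdiff(c("A", "B"), positive_is))]
  } else if ("name" %in% names(tr)) {
    if (!all(tr$name %in% c("A", "B")))
      stopf("labeled compartment track must use labels A/B")
    tr[, label := name]
  } else stopf("track needs a value or name column")
  comp <- vapply(seq_len(nrow(tss)), function(i) {
    hit <- tr[chrom == tss$chrom[i] & start <= tss$pos[i] &
                tss$pos[i] < end, label]
    if (length(hit)) hit[1] else "unassigned"
  }, character(1))
  data.table(gene = tss$gene, compartment = comp)
}

#' Classify compartment switches between two cell types
#'
#' Cross-tabulates per-gene assignments; genes unassigned in either cell
#' type are excluded.
#'
#' @param assign_a,assign_b data.tables gene, compartment from
#'   [assign_compartment()] for the two cell types (A = reference, e.g.
#'   iPSC; B = comparison, e.g. CM).
#' @return data.table gene, switch_class in {stable_A, stable_B, A_to_B,
#'   B_to_A}.
#' @export
classify_switch <- function(assign_a, assign_b) {
  a <- as.data.table(assign_a); b <- as.data.table(assign_b)
  m <- a[b, on = "gene", nomatch = NULL,
         .(gene, c1 = compartment, c2 = i.compartment)]
  m <- m[c1 %in% c("A", "B") & c2 %in% c("A", "B")]
  m[, switch_class := fifelse(c1 == "A" & c2 == "A", "stable_A",
                       fifelse(c1 == "B" & c2 == "B", "stable_B",
                        fifelse(c1 == "A" & c2 == "B", "A_to_B",
                                "B_to_A")))]
  m[, .(gene, switch_class)]
}

#' Expression differences between compartment-switch classes
#'
#' Per-class medians/means of log2 fold change, and two-sided Wilcoxon
#' rank-sum tests (normal approximation with tie correction) of each
#' switching class against its matched stable class (A_to_B vs stable_A,
#' B_to_A vs stable_B).
#'
#' @param switch_classes data.table gene, switch_class.
#' @param log2fc_table data.table gene, log2fc (e.g. from a differential
#'   expression analysis, comparison cell type relative to reference).
#' @return list: summary (data.table class, n, median_log2fc,
#'   mean_log2fc), tests (data.table comparison, p).
#' @export
switch_expression_test <- function(switch_classes, log2fc_table) {
  sc <- as.data.table(switch_classes)
  fc <- as.data.table(log2fc_table)
  d <- fc[sc, on = "gene", nomatch = NULL]
  summ <- d[, .(n = .N, median_log2fc = median(log2fc),
                mean_log2fc = mean(log2fc)), by = switch_class]
  pair_p <- function(c1, c2) {
    x <- d[switch_class == c1, log2fc]; y <- d[switch_class == c2, log2fc]
    if (length(x) < 2 || length(y) < 2) return(NA_real_)
    suppressWarnings(wilcox.test(x, y, exact = FALSE)$p.value)
  }
  tests <- data.table(
    comparison = c("A_to_B_vs_stable_A", "B_to_A_vs_stable_B",
                   "B_to_A_vs_stable_A", "A_to_B_vs_stable_B"),
    p = c(pair_p("A_to_B", "stable_A"), pair_p("B_to_A", "stable_B"),
          pair_p("B_to_A", "stable_A"), pair_p("A_to_B", "stable_B")))
  list(summary = summ[], tests = tests)
}

#' Fallback log2 fold change from TPM tables
#'
#' log2((mean TPM_b + c) / (mean TPM_a + c)) with pseudo-count c, for use
#' when no differential-expression table is supplied.
#'
#' @param tpm_a,tpm_b data.tables gene plus one column per replicate.
#' @param pseudo pseudo-count (default 1).
#' @return data.table gene, log2fc.
#' @export
log2fc_from_tpm <- function(tpm_a, tpm_b, pseudo = 1) {
  a <- as.data.table(tpm_a); b <- as.data.table(tpm_b)
  ma <- a[, .(gene, ma = rowMeans(.SD)), .SDcols = setdiff(names(a), "gene")]
  mb <- b[, .(gene, mb = rowMeans(.SD)), .SDcols = setdiff(names(b), "gene")]
  m <- ma[mb, on = "gene", nomatch = NULL]
  m[, .(gene, log2fc = log2((mb + pseudo) / (ma + pseudo)))]
}
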