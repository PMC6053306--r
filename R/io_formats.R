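# Readers and writers for the external formats the pipeline touches.
# Internal convention: 0-based half-open; ibed-style interaction tables
# arrive 1-based inclusive and are converted here. All errors name the
# offending line.

.read_tsv <- function(path, header = TRUE) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  fread(path, sep = "\t", header = header, data.table = TRUE,
        na.strings = c("NA", ""))
}

.check_coords <- function(dt, start_col, end_col, path, offset = 1L) {
  bad <- which(!is.finite(dt[[start_col]]) | !is.finite(dt[[end_col]]) |
                 dt[[end_col]] <= dt[[start_col]])
  if (length(bad))
    stopf("%s: malformed coordinates (%s >= %s) at data line %d",
          path, start_col, end_col, bad[1] + offset)
  invisible(dt)
}

#' Read an interaction table
#'
#' Supports two tab-separated dialects. \code{ibed}: fixed columns
#' bait_chr, bait_start, bait_end, bait_name, otherEnd_chr, otherEnd_start,
#' otherEnd_end, otherEnd_name, N_reads, score, with a header line; starts
#' are 1-based inclusive and converted to 0-based half-open.
#' \code{studytable}: column names mapped via \code{header_map}, a named
#' character vector from ibed names to the file's names.
#'
#' Trans-chromosomal records are parsed but flagged (\code{is_trans}); all
#' downstream analyses use cis records only.
#'
#' @param path file path.
#' @param dialect "ibed" or "studytable".
#' @param replicate replicate label attached to every record.
#' @param header_map named character vector for the studytable dialect.
#' @return data.table: gene, bait_chrom, bait_start, bait_end, other_chrom,
#'   other_start, other_end, N_reads, score, replicate, is_trans.
#' @export
read_interactions <- function(path, dialect = c("ibed", "studytable"),
                              replicate = NA_character_, header_map = NULL) {
  dialect <- match.arg(dialect)
  dt <- .read_tsv(path)
  ibed_cols <- c("bait_chr", "bait_start", "bait_end", "bait_name",
                 "otherEnd_chr", "otherEnd_start", "otherEnd_end",
                 "otherEnd_name", "N_reads", "score")
  if (dialect == "ibed") {
    if (!all(ibed_cols %in% names(dt)))
      stopf("%s: missing ibed columns: %s", path,
            paste(setdiff(ibed_cols, names(dt)), collapse = ", "))
  } else {
    if (is.null(header_map))
      stopf("studytable dialect requires a header_map")
    miss <- setdiff(header_map, names(dt))
    if (length(miss))
      stopf("%s: mapped columns absent from file: %s", path,
            paste(miss, collapse = ", "))
    setnames(dt, unname(header_map), names(header_map))
    for (col in setdiff(ibed_cols, names(dt))) dt[, (col) := NA]
  }
  out <- dt[, .(
    gene = as.character(bait_name),
    bait_chrom = as.character(bait_chr),
    bait_start = as.numeric(bait_start) - 1, bait_end = as.numeric(bait_end),
    other_chrom = as.character(otherEnd_chr),
    other_start = as.numeric(otherEnd_start) - 1,
    other_end = as.numeric(otherEnd_end),
    N_reads = as.numeric(N_reads), score = as.numeric(score)
  )]
  .check_coords(out, "bait_start", "bait_end", path)
  .check_coords(out, "other_start", "other_end", path)
  if (any(out$score < 0, na.rm = TRUE))
    stopf("%s: negative interaction score at data line %d", path,
          which(out$score < 0)[1] + 1L)
  out[, `:=`(replicate = replicate, is_trans = bait_chrom != other_chrom)]
  out[]
}

#' Write an interaction table in ibed format (1-based inclusive starts)
#' @param interactions data.table in the internal layout of
#'   [read_interactions()].
#' @param path output path.
#' @export
write_interactions <- function(interactions, path) {
  x <- as.data.table(interactions)
  out <- x[, .(bait_chr = bait_chrom, bait_start = bait_start + 1,
               bait_end = bait_end, bait_name = gene,
               otherEnd_chr = other_chrom, otherEnd_start = other_start + 1,
               otherEnd_end = other_end, otherEnd_name = ".",
               N_reads = if ("N_reads" %in% names(x)) N_reads else NA_real_,
               score = score)]
  fwrite(out, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Write interactions as a WashU longrange text track
#'
#' One line per interaction: \code{chrom start end target,score}, with
#' \code{target = chr:start-end} of the partner interval; sorted by
#' coordinate.
#' @param interactions internal interaction table (cis records).
#' @param path output path.
#' @export
write_washu_track <- function(interactions, path) {
  x <- as.data.table(interactions)
  if (!nrow(x)) { writeLines(character(0), path); return(invisible(path)) }
  bchr <- if ("bait_chrom" %in% names(x)) x$bait_chrom else x$chrom
  ochr <- if ("other_chrom" %in% names(x)) x$other_chrom else x$chrom
  lines <- x[, sprintf("%s\t%d\t%d\t%s:%d-%d,%g",
                       bchr, as.integer(bait_start),
                       as.integer(bait_end), ochr,
                       as.integer(other_start), as.integer(other_end),
                       ifelse(is.na(score), 0, score))]
  o <- order(bchr, x$bait_start, x$other_start)
  writeLines(lines[o], path)
  invisible(path)
}

#' Read a BED file (0-based half-open)
#'
#' @param path BED path; columns chrom, start, end and optionally name and a
#'   signed value.
#' @return data.table chrom, start, end (+ name, value when present).
#' @export
read_bed <- function(path) {
  dt <- .read_tsv(path, header = FALSE)
  if (ncol(dt) < 3) stopf("%s: BED needs >= 3 columns", path)
  setnames(dt, seq_len(min(ncol(dt), 5)),
           c("chrom", "start", "end", "name", "value")[seq_len(min(ncol(dt), 5))])
  dt[, `:=`(chrom = as.character(chrom), start = as.numeric(start),
            end = as.numeric(end))]
  .check_coords(dt, "start", "end", path, offset = 0L)
  dt[]
}

#' Write a BED file
#' @param dt data.table with chrom, start, end and optional further columns.
#' @param path output path.
#' @export
write_bed <- function(dt, path) {
  fwrite(as.data.table(dt), path, sep = "\t", quote = FALSE,
         col.names = FALSE, na = ".")
  invisible(path)
}

#' Read a bedGraph-style signed compartment track
#' @param path bedGraph path (chrom, start, end, value).
#' @return data.table chrom, start, end, value.
#' @export
read_bedgraph <- function(path) {
  dt <- .read_tsv(path, header = FALSE)
  if (ncol(dt) < 4) stopf("%s: bedGraph needs 4 columns", path)
  setnames(dt, 1:4, c("chrom", "start", "end", "value"))
  dt[, `:=`(chrom = as.character(chrom), start = as.numeric(start),
            end = as.numeric(end), value = as.numeric(value))]
  .check_coords(dt, "start", "end", path, offset = 0L)
  bad <- which(!is.finite(dt$value))
  if (length(bad)) stopf("%s: non-numeric value at data line %d", path, bad[1])
  dt[, seq_len(4), with = FALSE]
}

#' Read a TSS catalog (TSV: gene, chrom, pos, strand)
#' @param path TSV path with header.
#' @return data.table gene, chrom, pos, strand.
#' @export
read_tss_catalog <- function(path) {
  dt <- .read_tsv(path)
  req <- c("gene", "chrom", "pos", "strand")
  if (!all(req %in% names(dt)))
    stopf("%s: TSS catalog needs columns %s", path, paste(req, collapse = ", "))
  bad <- which(!dt$strand %in% c("+", "-"))
  if (length(bad)) stopf("%s: bad strand at data line %d", path, bad[1] + 1L)
  dt[, .(gene = as.character(gene), chrom = as.character(chrom),
         pos = as.numeric(pos), strand = as.character(strand))]
}

#' Read a minimal OBO ontology file
#'
#' Parses [Term] stanzas for id, name and is_a edges; checks the graph is a
#' DAG and that every is_a target exists.
#'
#' @param path OBO path.
#' @return list with \code{terms} (data.table id, name) and \code{edges}
#'   (data.table id, parent).
#' @export
read_obo_lite <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  ids <- character(0); names_ <- character(0)
  e_child <- character(0); e_parent <- character(0)
  cur <- NA_character_; in_term <- FALSE
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "[Term]") { in_term <- TRUE; cur <- NA_character_; next }
    if (grepl("^\\[", ln)) { in_term <- FALSE; next }
    if (!in_term || ln == "") next
    if (startsWith(ln, "id:")) {
      cur <- trimws(sub("^id:", "", ln))
      ids <- c(ids, cur); names_ <- c(names_, NA_character_)
    } else if (startsWith(ln, "name:")) {
      if (is.na(cur)) stopf("%s: name before id at line %d", path, i)
      names_[length(names_)] <- trimws(sub("^name:", "", ln))
    } else if (startsWith(ln, "is_a:")) {
      if (is.na(cur)) stopf("%s: is_a before id at line %d", path, i)
      tgt <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
      e_child <- c(e_child, cur); e_parent <- c(e_parent, tgt)
    }
  }
  terms <- data.table(id = ids, name = names_)
  edges <- data.table(id = e_child, parent = e_parent)
  orphan <- setdiff(edges$parent, terms$id)
  if (length(orphan))
    stopf("%s: is_a references unknown term(s): %s", path,
          paste(orphan, collapse = ", "))
  # cycle check: iteratively strip root terms (no outgoing is_a edge)
  remaining <- copy(edges)
  nodes <- terms$id
  while (length(nodes)) {
    roots <- setdiff(nodes, unique(remaining$id))
    if (!length(roots)) stopf("%s: cycle detected in is_a graph", path)
    nodes <- setdiff(nodes, roots)
    remaining <- remaining[!(parent %in% roots)]
  }
  list(terms = terms, edges = edges)
}

#' All ancestors (transitive is_a closure) of each ontology term
#' @param dag as returned by [read_obo_lite()].
#' @return named list term id -> character vector of ancestor ids
#'   (excluding the term itself).
#' @export
obo_ancestors <- function(dag) {
  parents <- split(dag$edges$parent, dag$edges$id)
  memo <- new.env(parent = emptyenv())
  anc <- function(id) {
    if (!is.null(memo[[id]])) return(memo[[id]])
    ps <- parents[[id]]
    res <- if (is.null(ps)) character(0)
           else unique(c(ps, unlist(lapply(ps, anc), use.names = FALSE)))
    memo[[id]] <- res
    res
  }
  setNames(lapply(dag$terms$id, anc), dag$terms$id)
}

#' Read a gene-association table (TSV: gene, term)
#' @param path TSV path with header columns gene and term.
#' @return data.table gene, term.
#' @export
read_gene_associations <- function(path) {
  dt <- .read_tsv(path)
  if (!all(c("gene", "term") %in% names(dt)))
    stopf("%s: association table needs columns gene, term", path)
  if (!nrow(dt)) stopf("%s: association table is empty", path)
  unique(dt[, .(gene = as.character(gene), term = as.character(term))])
}

#' Read a phased haplotype panel
#'
#' TSV with columns snp, chrom, pos and one 0/1 column per haplotype
#' (columns named hap1..hapH or anything else — every column beyond the
#' first three is a haplotype).
#'
#' @param path TSV path with header.
#' @return list: \code{meta} (data.table snp, chrom, pos) and \code{geno}
#'   (0/1 integer matrix, one row per variant).
#' @export
read_haplotype_panel <- function(path) {
  dt <- .read_tsv(path)
  req <- c("snp", "chrom", "pos")
  if (!all(req %in% names(dt)))
    stopf("%s: haplotype panel needs columns %s", path,
          paste(req, collapse = ", "))
  hap_cols <- setdiff(names(dt), req)
  if (!length(hap_cols)) stopf("%s: no haplotype columns", path)
  geno <- as.matrix(dt[, hap_cols, with = FALSE])
  if (!all(geno %in% c(0L, 1L)))
    stopf("%s: haplotype alleles must be 0/1 (unphased or multi-allelic %s",
          path, "input is not supported; supply phased biallelic haplotypes)")
  storage.mode(geno) <- "integer"
  rownames(geno) <- dt$snp
  list(meta = dt[, .(snp = as.character(snp), chrom = as.character(chrom),
                     pos = as.numeric(pos))],
       geno = geno)
}

#' Write a fragment map as BED (chrom, start, end, fragment id)
#' @param fragment_map fragment map table.
#' @param path output path.
#' @export
write_fragment_map <- function(fragment_map, path) {
  write_bed(as.data.table(fragment_map)[, .(chrom, start, end, frag_id)], path)
}

#' Read a fragment map written by [write_fragment_map()]
#' @param path BED path.
#' @return fragment map data.table.
#' @export
read_fragment_map <- function(path) {
  dt <- read_bed(path)
  if (!"name" %in% names(dt)) stopf("%s: fragment map needs an id column", path)
  fm <- dt[, .(chrom, start, end, frag_id = as.integer(name))]
  setkey(fm, chrom, start)
  fm[]
}
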