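# Synthetic PCHi-C study generator. Emulates the inputs of every pipeline
# stage at desk scale: an MboI-like fragment scaffold (mean fragment
# 422 bp), bait selection around simulated TSSs, distance-decaying true
# loops with replicate dropout and fragment jitter across two cell types
# (~55% shared), TAD and compartment tracks, peaks planted at loop anchors
# over a background rate, LD-block haplotypes with tag SNPs, eQTLs with a
# planted looping preference, and expression coupled to compartment and
# local peak density. Truth tables record every planted object so
# parameter-recovery tests can score the pipeline.

#' Simulation configuration
#'
#' Defaults define the simulated study conditions: 422 bp mean fragment
#' size, 10 kb minimum loop span, three replicates per cell type with
#' dropout, and ~55% of loops shared between cell types.
#'
#' @param seed RNG seed (every dataset is reproducible from it).
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @param mean_frag mean restriction-fragment size in bp (default 422).
#' @param genes_per_chrom genes simulated per chromosome.
#' @param mean_loops mean true loops per promoter (Poisson + 1).
#' @param alpha distance-decay exponent of loop spans (density ~ d^-alpha).
#' @param min_span,max_span loop span range in bp.
#' @param n_replicates replicates per cell type (default 3).
#' @param dropout per-replicate probability of missing a true loop.
#' @param jitter_prob probability a replicate reports the fragment
#'   adjacent to the true anchor.
#' @param noise_rate noise loops per replicate, as a fraction of the cell
#'   type's true loop count.
#' @param shared_frac fraction of true loops shared between cell types.
#' @param peak_background background peak rate per fragment (beta).
#' @param peak_anchor peak rate at true loop anchor fragments (pi_peak);
#'   set equal to \code{peak_background} for an unplanted (null) dataset.
#' @param tad_meanlog,tad_sdlog lognormal TAD size parameters (median
#'   exp(tad_meanlog), default 640 kb).
#' @param comp_mean_len mean compartment interval length in bp.
#' @param comp_switch_frac fraction of compartment intervals flipping sign
#'   in the second cell type.
#' @param n_haplotypes haplotype panel size.
#' @param ld_block_len LD block length in bp.
#' @param ld_block_vars variants per LD block.
#' @param ld_mut_rate per-haplotype mutation rate within a block.
#' @param n_tag_snps tag SNPs (one per planted LD block).
#' @param plant_snps_in_anchors place tag-SNP blocks inside distal anchor
#'   fragments of cell-type-B loops (TRUE) or at random (FALSE).
#' @param n_eqtl number of eQTL records.
#' @param pi_eqtl fraction of eQTLs planted inside an anchor of a loop of
#'   their own associated gene.
#' @param expr_comp_effect additive log-scale expression effect of the A
#'   compartment.
#' @param expr_peak_coef log-scale effect per peak within 300 kb of the
#'   TSS.
#' @param expr_gene_sd gene-level log-scale expression dispersion.
#' @param expr_sd replicate-level log-scale expression noise.
#' @param expr_zero_frac fraction of silent (0 TPM) genes.
#' @return config list.
#' @export
sim_config <- function(seed = 1L,
                       chrom_lengths = c(chrS1 = 8e6, chrS2 = 8e6),
                       mean_frag = 422,
                       genes_per_chrom = 60L,
                       mean_loops = 4,
                       alpha = 1.5,
                       min_span = 1e4,
                       max_span = 2e6,
                       n_replicates = 3L,
                       dropout = 0.2,
                       jitter_prob = 0.02,
                       noise_rate = 0.2,
                       shared_frac = 0.55,
                       peak_background = 0.05,
                       peak_anchor = 0.15,
                       tad_meanlog = log(6.4e5),
                       tad_sdlog = 0.35,
                       comp_mean_len = 8e5,
                       comp_switch_frac = 0.12,
                       n_haplotypes = 100L,
                       ld_block_len = 2e4,
                       ld_block_vars = 12L,
                       ld_mut_rate = 0.005,
                       n_tag_snps = 10L,
                       plant_snps_in_anchors = TRUE,
                       n_eqtl = 200L,
                       pi_eqtl = 0.5,
                       expr_comp_effect = 1.5,
                       expr_peak_coef = 0.04,
                       expr_gene_sd = 1.2,
                       expr_sd = 0.25,
                       expr_zero_frac = 0.15) {
  cfg <- as.list(environment())
  rates <- c(cfg$dropout, cfg$jitter_prob, cfg$shared_frac,
             cfg$peak_background, cfg$peak_anchor, cfg$comp_switch_frac,
             cfg$ld_mut_rate, cfg$pi_eqtl, cfg$expr_zero_frac)
  if (any(rates < 0 | rates > 1)) stopf("rates must lie in [0,1]")
  if (cfg$alpha <= 0) stopf("alpha must be > 0")
  if (cfg$min_span >= min(cfg$chrom_lengths))
    stopf("min_span exceeds the shortest chromosome")
  validate_layout(cfg$chrom_lengths)
  cfg
}

# inverse-CDF sampler for density ~ d^-alpha on [dmin, dmax]
sample_powerlaw <- function(n, alpha, dmin, dmax) {
  u <- runif(n)
  if (abs(alpha - 1) < 1e-12) {
    exp(log(dmin) + u * (log(dmax) - log(dmin)))
  } else {
    a1 <- 1 - alpha
    (dmin^a1 + u * (dmax^a1 - dmin^a1))^(1 / a1)
  }
}

.sim_cuts <- function(len, mean_frag) {
  # geometric spacing, mean = mean_frag
  n_guess <- ceiling(len / mean_frag * 1.3) + 50
  gaps <- rgeom(n_guess, 1 / mean_frag) + 1
  cuts <- cumsum(gaps)
  while (cuts[length(cuts)] < len) {
    gaps <- rgeom(n_guess, 1 / mean_frag) + 1
    cuts <- c(cuts, cuts[length(cuts)] + cumsum(gaps))
  }
  cuts[cuts < len]
}

.sim_domains <- function(layout, meanlog, sdlog) {
  rbindlist(lapply(names(layout), function(chr) {
    len <- layout[[chr]]
    pos <- 0; rows <- list()
    while (pos < len) {
      dsize <- min(rlnorm(1, meanlog, sdlog), len - pos)
      if (dsize < 5e4) break
      rows[[length(rows) + 1]] <-
        data.table(chrom = chr, start = pos, end = pos + dsize,
                   label = "domain")
      pos <- pos + dsize
      if (pos >= len) break
      sep <- if (runif(1) < 0.75) c(4e4, "boundary") else c(8e4, "gap")
      w <- min(as.numeric(sep[1]), len - pos)
      if (w > 0) {
        rows[[length(rows) + 1]] <-
          data.table(chrom = chr, start = pos, end = pos + w,
                     label = sep[2])
        pos <- pos + w
      }
    }
    rbindlist(rows)
  }))
}

.sim_compartments <- function(layout, mean_len) {
  rbindlist(lapply(names(layout), function(chr) {
    len <- layout[[chr]]
    pos <- 0; sgn <- sample(c(-1, 1), 1); rows <- list()
    while (pos < len) {
      w <- min(max(2e5, rexp(1, 1 / mean_len)), len - pos)
      rows[[length(rows) + 1]] <-
        data.table(chrom = chr, start = pos, end = pos + w,
                   value = sgn * runif(1, 0.2, 1.5))
      pos <- pos + w; sgn <- -sgn
    }
    rbindlist(rows)
  }))
}

#' Simulate a complete synthetic PCHi-C study
#'
#' @param config configuration from [sim_config()].
#' @return bundle list: layout, fragment_map, tss, baits, probe_ends,
#'   promoter_regions, interactions (nested list cell type -> replicate ->
#'   internal interaction table, promoter-summarised, fragment-level
#'   distal ends), domains, compartments (per cell type), peaks (per cell
#'   type), tpm (per cell type: gene + one column per replicate), panel,
#'   tag_snps, eqtls, truth (loops, eqtls, snp_blocks, config).
#' @export
simulate_dataset <- function(config = sim_config()) {
  set.seed(config$seed)
  layout <- config$chrom_lengths
  cells <- c("A", "B")

  ## fragment scaffold
  cuts <- lapply(layout, .sim_cuts, mean_frag = config$mean_frag)
  fm <- build_fragment_map(layout, cuts)

  ## genes: TSSs uniform within a margin, random strand
  margin <- min(2e5, min(layout) * 0.02)
  tss <- rbindlist(lapply(names(layout), function(chr) {
    n <- config$genes_per_chrom
    data.table(gene = character(n), chrom = chr,
               pos = sort(round(runif(n, margin, layout[[chr]] - margin))),
               strand = sample(c("+", "-"), n, replace = TRUE))
  }))
  tss[, gene := sprintf("g%04d", seq_len(.N))]

  ## baits and promoter regions
  sel <- select_bait_fragments(tss, fm)
  baits <- sel$baits
  prom <- merge_promoter_regions(baits, fm, tss)
  genes <- prom$gene
  tssg <- tss[gene %in% genes]

  ## true loops: span ~ d^-alpha, anchor = fragment containing tss +- d
  loops <- rbindlist(lapply(genes, function(g) {
    gi <- tssg[gene == g]
    n <- 1L + rpois(1, max(config$mean_loops - 1, 0))
    d <- sample_powerlaw(n, config$alpha, config$min_span, config$max_span)
    dir <- sample(c(-1, 1), n, replace = TRUE)
    anchor <- gi$pos + dir * d
    len <- layout[[gi$chrom]]
    anchor <- pmin(pmax(anchor, 1), len - 2)  # clip inside chromosome
    data.table(gene = g, chrom = gi$chrom, anchor = anchor)
  }))
  loops[, frag_id := locate_fragment(fm, chrom, anchor)]
  loops <- loops[!is.na(frag_id)]
  loops <- unique(loops, by = c("gene", "frag_id"))
  fmi <- as.data.table(fm)
  setorder(fmi, frag_id)  # row i <-> frag_id i
  loops <- fmi[, .(frag_id, start, end)][loops, on = "frag_id"]
  # drop loops whose anchor fragment touches the gene's own promoter
  loops <- prom[, .(gene, prom_start = start, prom_end = end)][
    loops, on = "gene"]
  loops <- loops[!(start < prom_end & prom_start < end)]
  loops[, loop_id := seq_len(.N)]
  cellmix <- runif(nrow(loops))
  loops[, cell_type := fifelse(cellmix < config$shared_frac, "shared",
                        fifelse(cellmix < config$shared_frac +
                                  (1 - config$shared_frac) / 2, "A", "B"))]

  ## per-replicate observations
  score_of <- function(n) round(5 + rexp(n, 1 / 3), 2)
  obs_tables <- list()
  for (ct in cells) {
    lt <- loops[cell_type %in% c("shared", ct)]
    reps <- list()
    for (r in seq_len(config$n_replicates)) {
      seen <- lt[runif(.N) >= config$dropout]
      if (nrow(seen)) {
        jit <- runif(nrow(seen)) < config$jitter_prob
        if (any(jit)) {
          shift <- sample(c(-1L, 1L), sum(jit), replace = TRUE)
          newid <- seen$frag_id[jit] + shift
          newid <- pmax(pmin(newid, max(fmi$frag_id)), 1L)
          ok <- fmi$chrom[newid] == seen$chrom[jit]
          newid[!ok] <- seen$frag_id[jit][!ok]
          seen$frag_id[jit] <- newid
          seen[jit, `:=`(start = fmi$start[newid], end = fmi$end[newid])]
        }
      }
      # independent noise loops
      n_noise <- round(config$noise_rate * nrow(lt))
      noise <- if (n_noise > 0) {
        ng <- sample(genes, n_noise, replace = TRUE)
        nd <- sample_powerlaw(n_noise, config$alpha, config$min_span,
                              config$max_span)
        ndir <- sample(c(-1, 1), n_noise, replace = TRUE)
        nt <- tssg[match(ng, gene)]
        npos <- pmin(pmax(nt$pos + ndir * nd, 1),
                     unname(layout[nt$chrom]) - 2)
        nid <- locate_fragment(fm, nt$chrom, npos)
        keep_n <- !is.na(nid)
        data.table(gene = ng[keep_n], chrom = nt$chrom[keep_n],
                   frag_id = nid[keep_n],
                   start = fmi$start[nid[keep_n]],
                   end = fmi$end[nid[keep_n]])
      } else NULL
      pr_of <- prom[match(c(seen$gene, noise$gene), gene)]
      tab <- data.table(
        gene = c(seen$gene, noise$gene),
        bait_chrom = pr_of$chrom,
        bait_start = pr_of$start, bait_end = pr_of$end,
        other_chrom = c(seen$chrom, noise$chrom),
        other_start = c(seen$start, noise$start),
        other_end = c(seen$end, noise$end),
        N_reads = rpois(nrow(seen) + length(noise$gene), 50),
        score = score_of(nrow(seen) + length(noise$gene)),
        replicate = sprintf("%s_rep%d", ct, r),
        is_trans = FALSE)
      # own-promoter overlaps can arise from noise; drop them
      tab <- tab[!(other_start < bait_end & bait_start < other_end)]
      reps[[sprintf("rep%d", r)]] <- tab
    }
    obs_tables[[ct]] <- reps
  }

  ## TADs and compartments
  domains <- .sim_domains(layout, config$tad_meanlog, config$tad_sdlog)
  comp_a <- .sim_compartments(layout, config$comp_mean_len)
  comp_b <- copy(comp_a)
  flip <- runif(nrow(comp_b)) < config$comp_switch_frac
  comp_b[flip, value := -value]
  compartments <- list(A = comp_a, B = comp_b)

  ## peaks: anchors of the cell type's loops at rate peak_anchor,
  ## other fragments at rate peak_background (exclusive)
  peaks <- list()
  for (ct in cells) {
    anchor_ids <- unique(loops[cell_type %in% c("shared", ct), frag_id])
    is_anchor <- fmi$frag_id %in% anchor_ids
    rate <- ifelse(is_anchor, config$peak_anchor, config$peak_background)
    hit <- runif(nrow(fmi)) < rate
    pk <- fmi[hit]
    # peak = centered sub-interval (<= 200 bp), fully inside its fragment
    pk[, p_s := start + pmax(0, floor((end - start - 200) / 2))]
    pk[, p_e := pmin(end, p_s + 200)]
    peaks[[ct]] <- pk[, .(chrom, start = p_s, end = p_e,
                          name = sprintf("%s_peak%d", ct, seq_len(.N)))]
  }

  ## haplotype panel with LD blocks; tag SNPs
  H <- config$n_haplotypes
  n_blocks <- max(config$n_tag_snps * 2L, 6L)
  anchors_b <- loops[cell_type %in% c("shared", "B")]
  # GWAS blocks are planted promoter-distal: skip anchors overlapping any
  # captured promoter region (such SNPs are excluded by the linker)
  if (nrow(anchors_b)) {
    pk_prom <- prom[, .(chrom, p_s = start, p_e = end)]
    in_any_prom <- vapply(seq_len(nrow(anchors_b)), function(i)
      pk_prom[chrom == anchors_b$chrom[i] & p_s < anchors_b$end[i] &
                anchors_b$start[i] < p_e, .N] > 0, logical(1))
    anchors_b <- anchors_b[!in_any_prom]
  }
  block_centers <- rbindlist(lapply(seq_len(n_blocks), function(bi) {
    planted <- config$plant_snps_in_anchors && bi <= config$n_tag_snps &&
      nrow(anchors_b) > 0
    if (planted) {
      a <- anchors_b[sample(.N, 1)]
      data.table(block = bi, chrom = a$chrom,
                 center = floor(midpoint(a$start, a$end)),
                 planted_gene = a$gene)
    } else {
      chr <- sample(names(layout), 1)
      data.table(block = bi, chrom = chr,
                 center = round(runif(1, 1e5, layout[[chr]] - 1e5)),
                 planted_gene = NA_character_)
    }
  }))
  panel_rows <- list(); geno_rows <- list()
  for (bi in seq_len(n_blocks)) {
    bc <- block_centers[block == bi]
    founder <- rbinom(H, 1, 0.5)
    offs <- sort(round(seq(-config$ld_block_len / 2,
                           config$ld_block_len / 2,
                           length.out = config$ld_block_vars)))
    for (v in seq_along(offs)) {
      alle <- as.integer(xor(founder, rbinom(H, 1, config$ld_mut_rate)))
      panel_rows[[length(panel_rows) + 1]] <- data.table(
        snp = sprintf("rs_b%02d_v%02d", bi, v), chrom = bc$chrom,
        pos = bc$center + offs[v], block = bi)
      geno_rows[[length(geno_rows) + 1]] <- alle
    }
  }
  meta <- rbindlist(panel_rows)
  geno <- do.call(rbind, geno_rows)
  rownames(geno) <- meta$snp
  panel <- list(meta = meta[, .(snp, chrom, pos)], geno = geno)
  classes <- c("arrhythmia", "myocardial_infarction", "heart_failure")
  tag_idx <- vapply(seq_len(config$n_tag_snps), function(bi) {
    which(meta$block == bi)[ceiling(config$ld_block_vars / 2)]
  }, integer(1))
  tag_snps <- data.table(
    snp = meta$snp[tag_idx], chrom = meta$chrom[tag_idx],
    pos = meta$pos[tag_idx],
    disease_class = rep(classes, length.out = length(tag_idx)))

  ## eQTLs with planted looping preference
  loops_b <- loops[cell_type %in% c("shared", "B")]
  eq <- rbindlist(lapply(seq_len(config$n_eqtl), function(i) {
    if (runif(1) < config$pi_eqtl && nrow(loops_b)) {
      a <- loops_b[sample(.N, 1)]
      data.table(snp = sprintf("eq%04d", i), chrom = a$chrom,
                 pos = round(runif(1, a$start, a$end - 1)),
                 gene = a$gene, planted = TRUE)
    } else {
      g <- sample(genes, 1)
      gi <- tssg[gene == g]
      repeat {
        p <- round(runif(1, 1, layout[[gi$chrom]] - 1))
        if (abs(p - gi$pos) >= config$min_span) break
      }
      data.table(snp = sprintf("eq%04d", i), chrom = gi$chrom, pos = p,
                 gene = g, planted = FALSE)
    }
  }))

  ## expression coupled to compartment and local peak density; the
  ## gene-level baseline and the silent set are shared across cell types
  ## so fold changes reflect the chromatin effects, not baseline noise
  tpm <- list()
  gene_base <- rnorm(nrow(tssg), 0, config$expr_gene_sd)
  zero <- runif(nrow(tssg)) < config$expr_zero_frac
  for (ct in cells) {
    comp <- assign_compartment(tssg, compartments[[ct]])
    pk <- peaks[[ct]]
    pk_mid <- pk[, .(chrom, start = midpoint(start, end),
                     end = midpoint(start, end) + 1)]
    setkey(pk_mid, chrom, start, end)
    wq <- tssg[, .(chrom, start = pos - 3e5, end = pos + 3e5,
                   xid = seq_len(.N))]
    dh <- foverlaps(wq, pk_mid, by.x = c("chrom", "start", "end"),
                    type = "any", nomatch = NULL)
    dens <- rep(0, nrow(tssg))
    if (nrow(dh)) {
      cnt <- dh[, .N, by = xid]
      dens[cnt$xid] <- cnt$N
    }
    mu <- 0.2 + gene_base +
      config$expr_comp_effect * (comp$compartment == "A") +
      config$expr_peak_coef * dens
    mat <- vapply(seq_len(config$n_replicates), function(r) {
      v <- exp(mu + rnorm(nrow(tssg), 0, config$expr_sd))
      v[zero] <- 0
      round(v, 3)
    }, numeric(nrow(tssg)))
    tp <- data.table(gene = tssg$gene)
    for (r in seq_len(config$n_replicates))
      tp[, (sprintf("rep%d", r)) := mat[, r]]
    tpm[[ct]] <- tp
  }

  list(layout = layout, fragment_map = fm, tss = tssg, baits = baits,
       probe_ends = sel$probe_ends, promoter_regions = prom,
       interactions = obs_tables, domains = domains,
       compartments = compartments, peaks = peaks, tpm = tpm,
       panel = panel, tag_snps = tag_snps,
       eqtls = eq[, .(snp, chrom, pos, gene)],
       truth = list(loops = loops, eqtls = eq,
                    snp_blocks = block_centers, config = config))
}

#' Score pipeline outputs against the planted truth
#'
#' @param bundle simulated bundle ([simulate_dataset()]).
#' @param consensus named list of consensus tables per cell type (any
#'   subset of A/B), matched to planted loops by gene identity and 1 kb
#'   extension overlap.
#' @param links optional SNP-gene link table to score link recall against
#'   planted tag-SNP blocks.
#' @param enrichment_result optional EnrichmentResult; its fold is
#'   compared with the planted peak_anchor/peak_background ratio.
#' @param ext extension used for truth matching (default 1000).
#' @return list of recovery metrics (loop recall/precision per cell type,
#'   link_recall, fold_error).
#' @export
truth_report <- function(bundle, consensus, links = NULL,
                         enrichment_result = NULL, ext = 1000) {
  truth <- bundle$truth$loops
  out <- list()
  for (ct in names(consensus)) {
    lt <- truth[cell_type %in% c("shared", ct)]
    cons <- as.data.table(consensus[[ct]])
    if (!nrow(lt)) next
    if (!nrow(cons)) {
      out[[paste0("recall_", ct)]] <- 0
      out[[paste0("precision_", ct)]] <- NA_real_
      next
    }
    match_one <- function(tt, cc) {
      # tt, cc: tables with gene, start, end; extension on both sides
      ck <- cc[, .(gene, start = start - ext, end = end + ext)]
      vapply(seq_len(nrow(tt)), function(i)
        ck[gene == tt$gene[i] & start < tt$end[i] + ext &
             tt$start[i] - ext < end, .N] > 0, logical(1))
    }
    rec <- match_one(lt[, .(gene, start, end)],
                     cons[, .(gene, start = other_start, end = other_end)])
    prec <- match_one(cons[, .(gene, start = other_start, end = other_end)],
                      lt[, .(gene, start, end)])
    out[[paste0("recall_", ct)]] <- mean(rec)
    out[[paste0("precision_", ct)]] <- mean(prec)
  }
  if (!is.null(links)) {
    planted <- bundle$truth$snp_blocks[!is.na(planted_gene)]
    if (nrow(planted)) {
      lk <- as.data.table(links)
      hit <- vapply(seq_len(nrow(planted)), function(i) {
        tgt <- planted$planted_gene[i]
        bi <- planted$block[i]
        any(lk$target_gene == tgt &
              startsWith(lk$snp, sprintf("rs_b%02d", bi)))
      }, logical(1))
      out$link_recall <- mean(hit)
    } else out$link_recall <- NA_real_
  }
  if (!is.null(enrichment_result)) {
    cfg <- bundle$truth$config
    planted_fold <- cfg$peak_anchor / cfg$peak_background
    out$fold_planted <- planted_fold
    out$fold_estimated <- enrichment_result$fold
    out$fold_error <- enrichment_result$fold - planted_fold
  }
  out
}

#' Write a simulated bundle to a directory in pipeline input formats
#'
#' Emits the fragment map (BED), TSS catalog and bait table (TSV),
#' per-replicate interaction files (ibed), domain BED, compartment
#' bedGraphs, peak BEDs, expression tables, the haplotype panel, tag SNP
#' and eQTL tables, and truth tables under truth/.
#'
#' @param bundle simulated bundle.
#' @param dir output directory (created).
#' @return dir, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  write_fragment_map(bundle$fragment_map, file.path(dir, "fragments.bed"))
  fwrite(bundle$tss, file.path(dir, "tss.tsv"), sep = "\t")
  fwrite(bundle$baits, file.path(dir, "baits.tsv"), sep = "\t")
  for (ct in names(bundle$interactions))
    for (r in names(bundle$interactions[[ct]]))
      write_interactions(bundle$interactions[[ct]][[r]],
                         file.path(dir, sprintf("interactions_%s_%s.ibed",
                                                ct, r)))
  write_bed(bundle$domains, file.path(dir, "tads.bed"))
  for (ct in names(bundle$compartments))
    fwrite(bundle$compartments[[ct]],
           file.path(dir, sprintf("compartments_%s.bedgraph", ct)),
           sep = "\t", col.names = FALSE)
  for (ct in names(bundle$peaks))
    write_bed(bundle$peaks[[ct]], file.path(dir, sprintf("peaks_%s.bed", ct)))
  for (ct in names(bundle$tpm))
    fwrite(bundle$tpm[[ct]], file.path(dir, sprintf("tpm_%s.tsv", ct)),
           sep = "\t")
  hap <- cbind(bundle$panel$meta, as.data.table(bundle$panel$geno))
  setnames(hap, 4:ncol(hap), sprintf("hap%d", seq_len(ncol(hap) - 3)))
  fwrite(hap, file.path(dir, "haplotypes.tsv"), sep = "\t")
  fwrite(bundle$tag_snps, file.path(dir, "tag_snps.tsv"), sep = "\t")
  fwrite(bundle$eqtls, file.path(dir, "eqtls.tsv"), sep = "\t")
  fwrite(bundle$truth$loops, file.path(dir, "truth", "loops.tsv"),
         sep = "\t")
  fwrite(bundle$truth$eqtls, file.path(dir, "truth", "eqtls.tsv"),
         sep = "\t")
  fwrite(bundle$truth$snp_blocks, file.path(dir, "truth", "snp_blocks.tsv"),
         sep = "\t")
  invisible(dir)
}
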