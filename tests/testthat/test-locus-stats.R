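mk_dag <- function(edges_child, edges_parent, ids = NULL) {
  ids <- ids %||% unique(c(edges_child, edges_parent))
  list(terms = data.table::data.table(id = ids, name = ids),
       edges = data.table::data.table(id = edges_child,
                                      parent = edges_parent))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

flat_dag <- function(terms) mk_dag(character(0), character(0), ids = terms)

test_that("hypergeometric enrichment reproduces the combinatorial oracle", {
  # universe 10, term annotates 5, set of 4 all annotated:
  # p = C(5,4) C(5,0) / C(10,4) = 5/210
  uni <- paste0("g", 1:10)
  assoc <- data.table::data.table(gene = uni[1:5], term = "T:1")
  res <- go_enrichment(uni[1:4], uni, flat_dag("T:1"), assoc)
  expect_equal(res$p, 5 / 210)
  expect_equal(res$term_set, 4L)

  # a term annotating the whole universe is never enriched
  assoc2 <- data.table::data.table(gene = uni, term = "T:1")
  res2 <- go_enrichment(uni[1:4], uni, flat_dag("T:1"), assoc2)
  expect_equal(res2$p, 1)
})

test_that("hypergeometric p equals exhaustive enumeration for all N <= 12", {
  for (N in c(5, 8, 12)) {
    uni <- paste0("g", seq_len(N))
    for (K in c(1, floor(N / 2), N - 1)) {
      for (n in c(1, floor(N / 2))) {
        assoc <- data.table::data.table(gene = uni[seq_len(K)], term = "T:1")
        gset <- uni[seq_len(n)]
        res <- go_enrichment(gset, uni, flat_dag("T:1"), assoc)
        hits <- sum(gset %in% uni[seq_len(K)])
        if (hits == 0) {
          expect_equal(nrow(res), 0L)
        } else {
          expect_equal(res$p, oracle_hyper_p(hits, K, N, n),
                       tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("annotations propagate to ancestor terms before counting", {
  dag <- mk_dag(c("T:child"), c("T:parent"))
  uni <- paste0("g", 1:10)
  assoc <- data.table::data.table(gene = "g1", term = "T:child")
  res <- go_enrichment("g1", uni, dag, assoc)
  expect_setequal(res$term, c("T:child", "T:parent"))
  expect_equal(res[res$term == "T:parent", ]$term_universe, 1L)
  expect_error(go_enrichment("g99", uni, dag, assoc), "subset")
})

test_that("BH adjustment matches a hand step-up oracle", {
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(41)
  p <- runif(50)
  expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  expect_error(bh_adjust(c(0.5, 1.2)), "0,1")
})

test_that("gene-set resampling hits saturation and planted enrichment", {
  pool <- paste0("g", 1:1000)
  r_sat <- suppressWarnings(
    geneset_resample_enrichment(pool[1:50], pool, pool,
                                n_iter = 50, seed = 1))
  expect_equal(r_sat$observed, 1)
  expect_equal(r_sat$fold, 1)

  expect_warning(
    r0 <- geneset_resample_enrichment(pool[1:50], pool, character(0),
                                      n_iter = 50, seed = 1),
    "sd")
  expect_equal(r0$observed, 0)

  # planted 2x over-representation: annotated rate 0.2 in the pool,
  # 0.4 among targets
  set.seed(43)
  ann <- pool[sort(sample(1000, 200))]
  targets <- c(sample(ann, 40), sample(setdiff(pool, ann), 60))
  r2 <- geneset_resample_enrichment(targets, pool, ann,
                                    n_iter = 1000, seed = 2)
  expect_equal(r2$observed, 0.4)
  expect_lt(abs(r2$fold - 2), 0.25)
  expect_error(geneset_resample_enrichment(c(pool, "gX")[1:1001], pool,
                                           ann), "subset")
})

eqtl_fixture <- function(seed = 3, pi_eqtl = 0.5, dropout = 0.2,
                         noise_rate = 0.2, n_eqtl = 250L,
                         genes_per_chrom = 40L,
                         chrom_lengths = c(c1 = 5e6, c2 = 5e6), ...) {
  cfg <- sim_config(seed = seed, chrom_lengths = chrom_lengths,
                    genes_per_chrom = genes_per_chrom, pi_eqtl = pi_eqtl,
                    dropout = dropout, noise_rate = noise_rate,
                    n_eqtl = n_eqtl, ...)
  b <- simulate_dataset(cfg)
  filt <- lapply(b$interactions$B, filter_min_distance)
  consB <- replicate_consensus(filt)
  eq <- filter_eqtls(b$eqtls, b$promoter_regions, b$tss)
  list(b = b, cons = consB, eq = eq)
}

test_that("promoter re-mapping preserves per-chromosome offset multisets", {
  fx <- eqtl_fixture()
  b <- fx$b; cons <- fx$cons
  tssmap <- unique(b$tss[, .(gene, chrom, tss = pos, strand)], by = "gene")
  offs <- promloop:::.interval_offsets(cons, tssmap)
  # one permutation, inspected directly via a tiny n_perm run with the
  # redraw method off: derangements never keep a promoter's own loops
  genes_by_chr <- split(unique(offs[, .(gene, chrom)])$gene,
                        unique(offs[, .(gene, chrom)])$chrom)
  set.seed(99)
  for (chr in names(genes_by_chr)) {
    g <- genes_by_chr[[chr]]
    idx <- promloop:::.derangement(length(g))
    expect_true(all(g[idx] != g))
    expect_setequal(g[idx], g)
  }
  expect_error(promloop:::.derangement(1), ">= 2")
})

test_that("a single interacting promoter per chromosome is an error", {
  cons <- data.table::data.table(
    gene = "g1", chrom = "c1", bait_start = 0, bait_end = 1000,
    other_start = 50000, other_end = 50400)
  tss <- data.table::data.table(gene = "g1", chrom = "c1", pos = 500,
                                strand = "+")
  eq <- data.table::data.table(snp = "e1", chrom = "c1", pos = 50100,
                               gene = "g1")
  expect_error(
    eqtl_loop_enrichment(eq, cons, tss, c(c1 = 1e6), n_perm = 5, seed = 1),
    ">= 2 promoters")
})

test_that("planted eQTL looping preference is recovered; null is calibrated", {
  # every eQTL planted inside an anchor of its own gene, noiseless; a
  # dense interactome so the conditional null concentrates well below 1
  fx <- eqtl_fixture(seed = 5, pi_eqtl = 1, dropout = 0, noise_rate = 0,
                     jitter_prob = 0, genes_per_chrom = 100L,
                     chrom_lengths = c(c1 = 8e6, c2 = 8e6),
                     n_eqtl = 400L, mean_loops = 5)
  r <- eqtl_loop_enrichment(fx$eq, fx$cons, fx$b$tss, fx$b$layout,
                            n_perm = 199, seed = 7)
  expect_equal(r$observed, 1)
  expect_true(is.na(r$z) || r$z > 3)  # NA only when every permutation is 0
  expect_lt(max(r$perm, na.rm = TRUE), 1)
  expect_equal(r$p_empirical, 1 / 200)

  # observed invariant under eQTL id relabeling
  eq2 <- data.table::copy(fx$eq)[, snp := rev(snp)]
  r2 <- eqtl_loop_enrichment(eq2, fx$cons, fx$b$tss, fx$b$layout,
                             n_perm = 5, seed = 7)
  expect_equal(r2$observed, r$observed)
})

test_that("redraw and derangement methods are both exposed", {
  fx <- eqtl_fixture(seed = 11)
  r1 <- eqtl_loop_enrichment(fx$eq, fx$cons, fx$b$tss, fx$b$layout,
                             n_perm = 20, seed = 3)
  r2 <- eqtl_loop_enrichment(fx$eq, fx$cons, fx$b$tss, fx$b$layout,
                             n_perm = 20, seed = 3, method = "redraw")
  expect_length(r1$perm, 20)
  expect_length(r2$perm, 20)
  expect_false(is.na(r1$observed))
})
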