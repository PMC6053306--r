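test_that("background sampling is uniform, forced and reproducible", {
  fm <- build_fragment_map(c(c1 = 5000), list(c1 = seq(500, 4500, 500)))
  # exclusion leaves exactly 3 fragments -> every draw returns that set
  pool <- background_pool(fm, data.table::data.table(
    chrom = "c1", start = 0, end = 3500))
  expect_equal(nrow(pool), 3L)
  draws <- sample_background_fragments(pool, 3, iterations = 5, seed = 1)
  for (d in draws) expect_setequal(d, pool$frag_id)

  # determinism
  p2 <- background_pool(fm)
  d1 <- sample_background_fragments(p2, 4, iterations = 10, seed = 42)
  d2 <- sample_background_fragments(p2, 4, iterations = 10, seed = 42)
  expect_identical(d1, d2)
  expect_error(sample_background_fragments(pool, 10, seed = 1), "smaller")

  # inclusion frequency ~ n/pool = 0.3; per-fragment 3 Monte-Carlo sd,
  # with a simultaneous 4.5 sd bound across the 10 fragments
  freq <- table(factor(unlist(sample_background_fragments(
    p2, 3, iterations = 1e4, seed = 7)), levels = p2$frag_id)) / 1e4
  mc_sd <- sqrt(0.3 * 0.7 / 1e4)
  expect_gte(sum(abs(freq - 0.3) < 3 * mc_sd), 9)
  expect_true(all(abs(freq - 0.3) < 4.5 * mc_sd))
})

test_that("enrichment saturates at 1 and counts overlaps exactly", {
  fm <- build_fragment_map(c(c1 = 4000), list(c1 = c(1000, 2000, 3000)))
  pool <- background_pool(fm)
  genome_wide <- data.table::data.table(chrom = "c1", start = 0, end = 4000)
  r <- suppressWarnings(
    enrichment(fm, genome_wide, pool, iterations = 10, seed = 1))
  expect_equal(r$observed, 1)
  expect_equal(r$null_mean, 1)
  expect_equal(r$fold, 1)

  # 4 distal fragments, peaks overlap exactly 2 -> observed 0.5
  peaks <- data.table::data.table(chrom = "c1", start = c(100, 2100),
                                  end = c(200, 2200))
  r2 <- suppressWarnings(
    enrichment(fm, peaks, pool, iterations = 10, seed = 1))
  expect_equal(r2$observed, 0.5)
})

test_that("zero null variance yields NA p with a warning", {
  fm <- build_fragment_map(c(c1 = 2000), list(c1 = 1000))
  pool <- background_pool(fm)
  peaks <- data.table::data.table(chrom = "c1", start = 0, end = 2000)
  expect_warning(r <- enrichment(fm, peaks, pool, iterations = 5, seed = 1),
                 "sd")
  expect_true(is.na(r$p))
})

test_that("TPM bins use the study boundaries, right-closed", {
  expect_equal(expression_bin(c(0, 0.5, 3, 3.01, 25, 26, 150, 151)),
               c(1L, 2L, 2L, 3L, 3L, 4L, 4L, 5L))
  expect_error(expression_bin(-1), ">= 0")
})

test_that("fold enrichment is invariant to duplicating fragments and peaks", {
  set.seed(31)
  fm <- build_fragment_map(c(c1 = 50000),
                           list(c1 = sort(sample(1:49999, 99))))
  pool <- background_pool(fm)
  peaks <- data.table::data.table(chrom = "c1",
                                  start = seq(500, 45000, 4000))
  peaks$end <- peaks$start + 300
  distal <- fm[fm$frag_id %in% sample(fm$frag_id, 20), ]
  r1 <- enrichment(distal, peaks, pool, iterations = 50, seed = 3)
  # duplicate every peak and every distal fragment record
  r2 <- enrichment(rbind(distal, distal), rbind(peaks, peaks), pool,
                   iterations = 50, seed = 3)
  expect_equal(r1$observed, r2$observed)
  expect_equal(r1$fold, r2$fold)
})

test_that("null-mean precision improves ~ 1/sqrt(iterations)", {
  set.seed(17)
  fm <- build_fragment_map(c(c1 = 2e5),
                           list(c1 = sort(sample(1:199999, 499))))
  pool <- background_pool(fm)
  peaks <- data.table::data.table(chrom = "c1",
                                  start = sort(sample(seq(0, 195000, 500), 60)))
  peaks$end <- peaks$start + 200
  distal <- fm[sample(nrow(fm), 40), ]
  sds <- vapply(c(20L, 320L), function(it) {
    ests <- vapply(1:30, function(s)
      enrichment(distal, peaks, pool, iterations = it,
                 seed = s)$null_mean, numeric(1))
    sd(ests)
  }, numeric(1))
  # 16x iterations -> ~4x smaller sd; allow generous slack
  expect_lt(sds[2], sds[1] / 2)
})

test_that("peak partitioning and the specificity grid behave on edge cases", {
  a <- data.table::data.table(chrom = "c1", start = c(100, 5000),
                              end = c(400, 5400))
  # identical feature sets: everything shared
  pp <- partition_peaks(a, a)
  expect_equal(nrow(pp$A_only), 0L)
  expect_equal(nrow(pp$B_only), 0L)
  expect_equal(nrow(pp$shared), 2L)
  # disjoint: nothing shared
  b <- data.table::data.table(chrom = "c1", start = 9000, end = 9400)
  pp2 <- partition_peaks(a, b)
  expect_equal(nrow(pp2$shared), 0L)
  expect_equal(nrow(pp2$A_only), 2L)

  fm <- build_fragment_map(c(c1 = 20000), list(c1 = seq(1000, 19000, 1000)))
  pool <- background_pool(fm)
  sets <- list(
    A_specific = data.table::data.table(other_chrom = "c1",
                                        other_start = 100, other_end = 900),
    B_specific = data.table::data.table(other_chrom = "c1",
                                        other_start = 9100,
                                        other_end = 9900),
    shared = data.table::data.table(other_chrom = "c1",
                                    other_start = 15100, other_end = 15900))
  grid <- suppressWarnings(
    specificity_matrix(sets, a, b, pool, fm, iterations = 20, seed = 2))
  # each populated cell equals an independent cellwise enrichment run
  one <- grid[grid$interaction_class == "A_specific" &
                grid$feature_class == "A_only", ]
  direct <- suppressWarnings(
    enrichment(distal_fragment_table(sets$A_specific, fm),
               pp2$A_only, pool, iterations = 20,
               seed = unique(one$seed)))
  expect_equal(one$observed, direct$observed)
  expect_equal(one$fold, direct$fold)
})

test_that("expression/peak-density correlation matches a rank-formula oracle", {
  tss <- data.table::data.table(gene = paste0("g", 1:20), chrom = "c1",
                                pos = seq(1e6, 20e6, 1e6), strand = "+")
  set.seed(19)
  # peak counts proportional to gene index + noise
  peaks <- data.table::rbindlist(lapply(1:20, function(i) {
    n <- i + rpois(1, 2)
    data.table::data.table(chrom = "c1",
                           start = tss$pos[i] + round(runif(n, -2e5, 2e5)))
  }))
  peaks$end <- peaks$start + 200
  tpm <- data.table::data.table(gene = tss$gene, tpm = (1:20)^1.5)
  r <- peak_density_expression_corr(tpm, peaks, tss)
  expect_gt(r$rho, 0.8)

  # reversed expression -> rho flips sign
  tpm_rev <- data.table::data.table(gene = tss$gene, tpm = rev((1:20)^1.5))
  r_rev <- peak_density_expression_corr(tpm_rev, peaks, tss)
  expect_equal(r_rev$rho, -r$rho)

  # oracle: Spearman = Pearson on average ranks
  cnt <- vapply(1:20, function(i)
    sum(peaks$chrom == "c1" &
          abs((peaks$start + peaks$end) / 2 - tss$pos[i]) <= 3e5),
    numeric(1))
  expect_equal(r$rho, cor(rank(tpm$tpm), rank(cnt)), tolerance = 1e-12)

  # gene filter respected
  r3 <- peak_density_expression_corr(tpm, peaks, tss,
                                     genes_with_interactions = tss$gene[1:10])
  expect_equal(r3$n, 10L)
  expect_error(peak_density_expression_corr(
    tpm, peaks, tss, genes_with_interactions = tss$gene[1:2]), ">= 3")
})

test_that("binned enrichment runs per bin and skips empty bins", {
  fm <- build_fragment_map(c(c1 = 1e5), list(c1 = seq(400, 99600, 400)))
  pool <- background_pool(fm)
  cons <- data.table::data.table(
    gene = c("g1", "g2", "g3"), chrom = "c1",
    bait_start = 0, bait_end = 400,
    other_start = c(20000, 50000, 80000),
    other_end = c(20400, 50400, 80400))
  tpm <- data.table::data.table(gene = c("g1", "g2", "g3"),
                                tpm = c(0, 10, 200))
  peaks <- data.table::data.table(chrom = "c1", start = 20000, end = 20400)
  w <- testthat::capture_warnings(
    res <- binned_enrichment(tpm, cons, peaks, pool, fm,
                             iterations = 10, seed = 1))
  expect_length(grep("empty", w), 2L)  # bins 2 and 4 are empty
  expect_setequal(res$bin, c(1L, 3L, 5L))
  expect_equal(res$observed[res$bin == 1], 1)  # g1's fragment has the peak
  expect_equal(res$observed[res$bin == 3], 0)
})
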