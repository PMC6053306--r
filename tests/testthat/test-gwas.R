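test_that("r-squared reproduces hand-computed LD and label symmetry", {
  a <- rep(c(1L, 0L), each = 50)
  expect_equal(r_squared(a, a), 1)
  expect_equal(r_squared(a, 1L - a), 1)  # allele labels irrelevant

  # haplotype table AB=40, Ab=10, aB=10, ab=40 (H=100):
  # D = 0.40 - 0.25 = 0.15, r2 = 0.15^2 / 0.5^4 = 0.36
  x <- rep(c(1L, 1L, 0L, 0L), c(40, 10, 10, 40))
  y <- rep(c(1L, 0L, 1L, 0L), c(40, 10, 10, 40))
  expect_equal(r_squared(x, y), 0.36)

  expect_true(is.na(r_squared(rep(0L, 10), rep(c(0L, 1L), 5))))
  expect_error(r_squared(c(0L, 1L), c(0L, 1L, 1L)), "length")
  expect_error(r_squared(c(0L, 2L), c(0L, 1L)), "0/1")
})

test_that("r-squared equals the squared Pearson correlation", {
  set.seed(23)
  for (i in 1:50) {
    h <- 2 * sample(10:60, 1)
    a <- rbinom(h, 1, runif(1, 0.1, 0.9))
    b <- as.integer(xor(a, rbinom(h, 1, runif(1, 0, 0.5))))
    if (length(unique(a)) < 2 || length(unique(b)) < 2) next
    expect_equal(r_squared(a, b), cor(a, b)^2, tolerance = 1e-12)
  }
})

sim_panel <- function(n_var = 20, H = 60, chrom = "c1",
                      pos = NULL, founder_p = 0.5, mut = 0.1) {
  if (is.null(pos)) pos <- sort(sample(1e5:2e5, n_var))
  founder <- rbinom(H, 1, founder_p)
  geno <- t(vapply(seq_len(n_var), function(i)
    as.integer(xor(founder, rbinom(H, 1, mut))), integer(H)))
  meta <- data.table::data.table(snp = paste0("v", seq_len(n_var)),
                                 chrom = chrom, pos = pos)
  rownames(geno) <- meta$snp
  list(meta = meta, geno = geno)
}

test_that("LD expansion matches a brute-force all-pairs filter", {
  set.seed(29)
  pan <- sim_panel()
  tags <- data.table::data.table(snp = "v10", chrom = "c1",
                                 pos = pan$meta$pos[10],
                                 disease_class = "arrhythmia")
  got <- ld_expand(tags, pan, window = 5e4, r2_min = 0.5, maf_min = 0.01)
  # oracle: direct r2/MAF/window filter over every panel variant
  tvec <- pan$geno[10, ]
  want <- vapply(seq_len(20), function(k) {
    if (k == 10) return(TRUE)
    if (abs(pan$meta$pos[k] - pan$meta$pos[10]) > 5e4) return(FALSE)
    p <- mean(pan$geno[k, ]); maf <- min(p, 1 - p)
    r2 <- suppressWarnings(cor(tvec, pan$geno[k, ])^2)
    !is.na(r2) && r2 > 0.5 && maf >= 0.01
  }, logical(1))
  expect_setequal(got$snp, pan$meta$snp[want])
  expect_equal(got[got$snp == "v10", ]$r2, 1)

  # a duplicated-column variant is always included with r2 = 1
  pan2 <- pan
  pan2$geno[11, ] <- pan2$geno[10, ]
  got2 <- ld_expand(tags, pan2, r2_min = 0.9)
  expect_true("v11" %in% got2$snp)
  expect_equal(got2[got2$snp == "v11", ]$r2, 1)

  # with thresholds dropped, every polymorphic variant in window returns
  got3 <- ld_expand(tags, pan, r2_min = 0, maf_min = 0)
  poly <- apply(pan$geno, 1, function(v) length(unique(v)) > 1)
  inwin <- abs(pan$meta$pos - pan$meta$pos[10]) <= 5e4
  expect_setequal(got3$snp, pan$meta$snp[(poly & inwin) |
                                           pan$meta$snp == "v10"])

  # absent tag is skipped with a warning
  badtag <- data.table::data.table(snp = "nope", chrom = "c1", pos = 1,
                                   disease_class = "hf")
  expect_warning(empty <- ld_expand(badtag, pan), "absent")
  expect_equal(nrow(empty), 0L)
})

test_that("tag alone in the window yields only itself", {
  pan <- sim_panel(n_var = 2, pos = c(1e5, 9e5))
  tags <- data.table::data.table(snp = "v1", chrom = "c1", pos = 1e5,
                                 disease_class = "arrhythmia")
  got <- ld_expand(tags, pan)
  expect_equal(got$snp, "v1")
})

mk_cons <- function(gene, os, oe, bs, be, chrom = "c1") {
  data.table::data.table(gene = gene, chrom = chrom, bait_start = bs,
                         bait_end = be, other_start = os, other_end = oe,
                         support = 2L, score = 6)
}

test_that("SNP linking excludes promoter SNPs and honors the 1 kb extension", {
  pr <- data.table::data.table(gene = c("gA", "gB"), chrom = "c1",
                               start = c(1000, 50000), end = c(2000, 51000),
                               strand = "+")
  cons <- mk_cons("gA", 30000, 30400, 1000, 2000)
  snps <- data.table::data.table(
    snp = c("s_in_prom", "s_in_frag", "s_800bp", "s_far"),
    chrom = "c1", pos = c(1500, 30100, 29200, 40000),
    disease_class = "arrhythmia")
  links <- link_snps(snps, cons, pr)
  # promoter-resident SNP excluded entirely; 800 bp outside the fragment
  # still linked through the extension; distant SNP unlinked
  expect_setequal(links$snp, c("s_in_frag", "s_800bp"))
  expect_equal(unique(links$target_gene), "gA")
  expect_equal(links[links$snp == "s_in_frag", ]$dist_bp,
               abs(30100 - 1500))

  # raising ext never loses links
  l0 <- link_snps(snps, cons, pr, ext = 0)
  l2 <- link_snps(snps, cons, pr, ext = 2000)
  expect_true(all(l0$snp %in% l2$snp))
  expect_gte(nrow(l2), nrow(l0))
})

test_that("skip counts use the strict interval and exclude the target gene", {
  tss <- data.table::data.table(
    gene = c("gT", "gT", "g1", "g2", "g3"), chrom = "c1",
    pos = c(1500, 25000, 10000, 20000, 90000), strand = "+")
  links <- data.table::data.table(
    snp = c("sA", "sB"), chrom = "c1", pos = c(30000, 2500),
    target_gene = "gT", prom_start = c(1000, 1000),
    prom_end = c(2000, 2000))
  n <- skip_count(links, tss)
  # sA..promoter edge (2000, 30000): TSSs of g1, g2 inside; gT's second
  # TSS at 25,000 not counted
  expect_equal(n[1], 2L)
  # sB at 2,500 adjacent to the promoter: nothing strictly between
  expect_equal(n[2], 0L)
})

test_that("link summaries match brute-force tabulation", {
  dom <- data.table::data.table(chrom = "c1", start = c(0, 60000),
                                end = c(50000, 120000), label = "domain")
  links <- data.table::data.table(
    snp = c("s1", "s1", "s2"), chrom = "c1", pos = c(30000, 30000, 70000),
    target_gene = c("gA", "gB", "gA"),
    prom_start = c(1000, 45000, 100000), prom_end = c(2000, 46000, 101000),
    n_skipped = c(2L, 0L, 1L))
  links$dist_bp <- abs(links$pos - (links$prom_start + links$prom_end) / 2)
  s <- link_summary(links, dom)
  expect_equal(s$n_snps, 2L)
  expect_equal(s$n_genes, 2L)
  expect_equal(s$median_dist, sort(links$dist_bp)[2])
  expect_equal(unname(s$genes_per_snp["2"]), 1L)  # s1 contacts 2 genes
  expect_equal(s$pct_skipping, 100 * 2 / 3)
  # same-TAD: s1-gA (both in first domain) and s2-gA (both in second):
  # s1-gB promoter at 45,500 same domain as SNP -> also same TAD
  expect_equal(s$pct_same_tad, 100)
  empty <- link_summary(links[0])
  expect_true(is.na(empty$n_snps))
})

test_that("planted anchor SNPs are recovered with the planted target gene", {
  cfg <- sim_config(seed = 17, chrom_lengths = c(c1 = 3e6, c2 = 3e6),
                    genes_per_chrom = 20L, dropout = 0, noise_rate = 0,
                    jitter_prob = 0, n_tag_snps = 8L)
  b <- simulate_dataset(cfg)
  consB <- replicate_consensus(b$interactions$B)
  ld <- ld_expand(b$tag_snps, b$panel)
  links <- link_snps(ld, consB, b$promoter_regions)
  tr <- truth_report(b, list(B = consB), links = links)
  expect_equal(tr$link_recall, 1)
  expect_equal(tr$recall_B, 1)
})
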