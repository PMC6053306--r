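library(data.table)

# Brute-force replicate-consensus oracle: all-pairs overlap graph of
# 1 kb-extended distal intervals within each gene, transitive closure by
# BFS, clusters with >= min_support distinct replicates emitted with the
# un-extended envelope. Independent of the sweep-based implementation.
oracle_consensus <- function(per_replicate, ext = 1000, min_support = 2L) {
  labs <- names(per_replicate)
  all <- rbindlist(lapply(labs, function(l) {
    d <- as.data.table(per_replicate[[l]])
    d[, replicate := l]
    d
  }), use.names = TRUE, fill = TRUE)
  out <- list()
  for (g in unique(all$gene)) {
    d <- all[gene == g]
    n <- nrow(d)
    es <- d$other_start - ext; ee <- d$other_end + ext
    adj <- outer(seq_len(n), seq_len(n),
                 function(i, j) es[i] < ee[j] & es[j] < ee[i])
    comp <- rep(NA_integer_, n); cid <- 0L
    for (i in seq_len(n)) {
      if (!is.na(comp[i])) next
      cid <- cid + 1L
      queue <- i
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        if (!is.na(comp[v])) next
        comp[v] <- cid
        queue <- c(queue, which(adj[v, ] & is.na(comp)))
      }
    }
    for (k in seq_len(cid)) {
      m <- which(comp == k)
      if (length(unique(d$replicate[m])) >= min_support)
        out[[length(out) + 1]] <- data.table(
          gene = g, other_start = min(d$other_start[m]),
          other_end = max(d$other_end[m]),
          support = length(unique(d$replicate[m])))
    }
  }
  res <- rbindlist(out)
  if (!nrow(res))
    res <- data.table(gene = character(), other_start = numeric(),
                      other_end = numeric(), support = integer())
  setorderv(res, c("gene", "other_start", "other_end", "support"))
  res
}

# random per-replicate interaction tables for a handful of genes; distal
# intervals drawn so that chance adjacency exercises the clustering
random_replicate_set <- function(n_rep = 3, n_genes = 3, n_per = 8,
                                 span = 5e4) {
  genes <- paste0("g", seq_len(n_genes))
  reps <- lapply(seq_len(n_rep), function(r) {
    n <- sample(2:n_per, 1)
    g <- sample(genes, n, replace = TRUE)
    s <- round(runif(n, 0, span))
    w <- round(runif(n, 100, 900))
    data.table(gene = g, bait_chrom = "c1", bait_start = 0, bait_end = 500,
               other_chrom = "c1", other_start = s, other_end = s + w,
               score = round(runif(n, 5, 20), 2))
  })
  names(reps) <- paste0("rep", seq_len(n_rep))
  reps
}

# exhaustive hypergeometric upper-tail p by enumerating all draws
oracle_hyper_p <- function(hits, K, N, n) {
  # P(X >= hits) with X ~ Hypergeom(N, K, n), by direct combinatorial sum
  ks <- hits:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# hand step-up BH adjustment, independent of stats::p.adjust
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# tiny deterministic fragment map on one chromosome
toy_map <- function(len = 10000, cuts = c(2000, 4000, 6000, 8000),
                    chrom = "c1") {
  cp <- list(cuts); names(cp) <- chrom
  layout <- len; names(layout) <- chrom
  build_fragment_map(layout, cp)
}
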