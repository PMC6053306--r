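---
title: "Downstream analysis of promoter capture Hi-C interaction maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Downstream analysis of promoter capture Hi-C interaction maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promloop)
library(data.table)
```

## The problem

Promoter capture Hi-C (PCHi-C) enriches a Hi-C library for ligation
products containing promoter "bait" restriction fragments, giving
fragment-resolution maps of which distal regions each promoter touches.
With a 4-cutter enzyme such as MboI the fragments average ~422 bp, so a
distal interacting fragment often pins down a single regulatory element.
The scientific payoff is downstream of the interaction calls: deciding
which calls are reproducible, placing them in the context of TADs and
A/B compartments, asking whether interacting fragments are enriched for
chromatin marks, and — the headline application — walking from a
disease-associated variant in a distal fragment, through the loop, to
the promoter it physically contacts, which is frequently *not* the
nearest gene.

promloop implements that downstream layer. Interaction significance
itself (the CHiCAGO model), TAD calling, compartment PCA, peak calling
and differential expression are consumed as inputs, never recomputed.

## Coordinate model and promoter summarisation

All intervals are 0-based half-open internally; ibed-style interaction
tables arrive 1-based inclusive and are converted at the I/O boundary.
Bait design follows the capture-probe logic: restriction fragments
longer than 200 bp overlapping ±10 kb of a TSS are eligible; of TSSs
closer than 1 kb to each other only one is retained (we keep the
smallest coordinate — the rule's tie-break is otherwise unspecified);
the four fragment *ends* (cut-site boundaries) closest to the TSS are
selected, a fragment contributing one end before its second end is
considered. A gene's promoter region ("merged TSS") is the envelope of
its bait fragments, and genes annotated to identical bait fragments are
reported individually.

## Replicate consensus

An interaction is retained when it appears, at the same gene, in at
least 2 of 3 replicates with distal fragments mapping within 1 kb of
each other. Concretely each distal fragment is extended by 1 kb on both
sides and records whose extended intervals overlap by ≥1 bp are matched
(extended-vs-extended, the pairToPair convention). Matching is
transitive-closure clustering within a gene: a chain a–b, b–c merges all
three even if a and c do not directly overlap. The emitted interval is
the un-extended envelope of the cluster, the score the per-replicate
maximum. Two further rules:

* the ≥10 kb span filter is applied per replicate, *before* consensus.
  Span distance is measured between the promoter-region midpoint and the
  distal-interval midpoint — the reference points are otherwise
  unspecified, and midpoints keep the measure symmetric in both ends;
* only the distal end is extended; bait ends are matched by gene
  identity. We read "each promoter-interacting fragment" as the non-bait
  fragment, and flag this as the one genuinely ambiguous reading (the
  alternative, extending both ends, only relaxes bait matching that gene
  identity already handles).

A cell type A consensus interaction is *A-specific* when no record for
the same gene in *any* replicate of the other cell type overlaps it
under the same extension rule — presence in a single sub-threshold
replicate is enough to make it shared.

Distal ends are categorised as P-promoter (the distal interval contains
a captured gene's TSS), P-proximal (overlaps the captured region but no
TSS) or P-distal (outside the captured region).

## TADs and compartments

An interaction is intra-TAD when its entire span (leftmost to rightmost
coordinate of both ends) lies inside a single domain, inter-TAD when its
two ends overlap exactly two different domains. Ends falling in
boundaries or gaps, or straddling a domain edge, are reported as
unassigned rather than folded into either class — how such ends were
counted in the original percentages is not stated, so we keep them
visible. Genes are anchored to compartments by their TSS; the
eigenvector sign convention (which sign is "A") must be supplied by the
caller and is never inferred from the data. Switch classes are the
cross-tabulation of the two cell types' labels, and expression
differences between switching and stable classes use the two-sided
Wilcoxon rank-sum test with normal approximation and tie correction.

## Randomized-background enrichment

The enrichment statistic for a chromatin feature is the proportion of
distinct promoter-interacting distal fragments (fragment-level, not
extended) overlapping ≥1 peak, compared to random draws of the same
number of fragments from a background pool that excludes captured
promoter regions (and any user-supplied unmappable regions). With 100
iterations (the default) the fold enrichment is observed / null mean and
the Z statistic (observed − null mean) / null sd. The Z-test is
one-sided in the direction of the observed deviation; the sidedness is
not stated in the figure legends we emulate, and a one-sided tail in the
observed direction is the permissive reading (calibration checks below
therefore count rejections in the enrichment direction only, which is
the pre-specified one-sided test). Expression-binned enrichment
partitions genes at 0, (0,3], (3,25], (25,150] and (150,∞) TPM —
the boundary closure is not stated; we close on the right. The 3×3
specificity grid crosses interaction classes (A-specific, B-specific,
shared) with feature classes (a peak is "shared" when it overlaps ≥1 bp
of any peak of the other cell type), each cell an independent enrichment
run with matched background.

## Variants to genes

Tag SNPs are expanded over a phased haplotype panel: every variant
within ±50 kb of the tag with r² > 0.9 and MAF ≥ 0.01 is retained, the
tag itself always (r² = 1), de-duplicated per disease class keeping the
highest r². r² is D²/(pA pa pB pb), identically the squared Pearson
correlation of the 0/1 haplotype vectors. Unphased input is rejected
rather than approximated. LD SNPs inside any captured promoter region
are set aside; the rest are linked to a target gene when they fall
inside the 1 kb-extended distal interval of a consensus interaction
(SNP linking is the one analysis run on extended intervals, to be
inclusive). Per link we report the SNP-to-promoter-midpoint distance,
whether SNP and promoter midpoint share a TAD, and the number of
distinct other genes with a TSS strictly between the SNP and the nearest
promoter edge ("skipped" promoters).

## Permutation and resampling nulls

**eQTL–loop enrichment.** Among eQTLs overlapping at least one
promoter-distal consensus interval, the observed statistic is the
fraction overlapping an interval belonging to their own associated gene.
The null re-maps each promoter's interaction set to a different
promoter, preserving each interval's signed, strand-aware offset from
the TSS. Whether the original analysis used a global derangement or
independent re-draws is not stated: we default to a uniform random
derangement within each chromosome (sampled by rejection), which
guarantees no promoter keeps its own interactions, and expose
independent re-draws as `method = "redraw"`. Re-mapped intervals falling
outside the chromosome are dropped and the denominator recomputed.
Besides the Z-based p we always report the empirical p,
(#{permuted ≥ observed} + 1) / (n_perm + 1).

**Gene-set resampling.** The observed fraction of target genes in an
annotated set is compared to draws of the same size, without
replacement, from the pool of genes with at least one promoter-distal
interaction (draws are not required to be expressed, matching the
original design).

**GO enrichment.** Direct gene–term annotations are propagated to every
ancestor along is_a edges (the OBO subset parser checks acyclicity),
then each term with ≥1 hit in the gene set gets an upper-tail
hypergeometric p against the universe, adjusted by Benjamini–Hochberg
across tested terms.

## The synthetic study

`simulate_dataset(sim_config())` generates a complete two-cell-type
study: a fragment scaffold with geometric cut spacing (mean 422 bp),
baited TSSs, true loops per promoter with power-law spans (density ∝
d^−α, α = 1.5, truncated at 10 kb and 2 Mb), three replicates per cell
type each observing a loop with probability 1 − q (q = 0.2), occasional
reporting of the adjacent fragment (2%) and independent noise calls
(20% of the true count); ~55% of loops shared between cell types; TAD
tilings with lognormal domain sizes (median 640 kb) separated by
boundaries and occasional gaps; signed compartment tracks with 12% of
intervals flipping between cell types; peaks planted at loop anchors
with probability π_peak = 0.15 against a background rate β = 0.05
(exclusively, so the planted fold is π_peak/β); LD blocks copied from
founder haplotypes with 0.5% mutation; tag SNPs planted in
promoter-distal loop anchors; eQTLs placed inside an anchor of their own
gene with probability π_eqtl = 0.5; and log-normal expression with a
shared gene baseline plus compartment (+1.5 log units in A) and local
peak-density effects.

What it does *not* emulate: genomic sequence and mappability structure,
CHiCAGO's read-count noise model (scores are decorative), biological
covariance between replicates beyond shared truth, population structure
in the haplotype panel, and trans interactions. Passing recovery tests
therefore demonstrates that the statistics recover planted parameters
under clean sampling assumptions — not that the pipeline is robust to
every artefact of real capture data.

## Numerical and design choices

* Overlap everywhere means ≥1 bp intersection of half-open intervals;
  touching intervals do not overlap.
* Randomized stages take an explicit seed, record it in their results,
  and the full pipeline is byte-identical across reruns with the same
  seed.
* Zero null standard deviation (saturated or degenerate backgrounds)
  yields `p = NA` with a warning rather than an arbitrary p.
* Monomorphic variants have undefined r² and return NA; the Spearman
  correlation of a constant vector is likewise NA.
* The derangement null requires ≥2 interacting promoters per chromosome
  and says so.
* Empty expression bins and genes without eligible bait fragments are
  skipped with warnings, never silently.

## Problem sizes used in the checks

The test-suite and the acceptance script run the generator at sizes
chosen so each statistical target is well-estimated: ~800 promoters
(≥2,000 true loops) for the dropout-recovery closed form; 5,000
promoters with two loops each for the planted-fold recovery, which keeps
planted anchors ~2% of the background pool so the analytic target
π_peak/β remains valid; 200 promoters and 400 eQTLs for the planted
permutation test, dense enough that the conditional null concentrates
well below 1; and 100–200 repeated small runs for the calibration
checks. The planted-recovery runs disable noise loops and jitter because
the closed-form expectations (binomial recovery, π_peak/β, observed
proportion 1.0) are derived under dropout-only sampling; the default
conditions keep both on.

## Known limitations

* Consensus clusters merge any same-gene calls within 2 kb; in dense
  interactomes an envelope can span several fragments, which slightly
  dilutes fragment-level enrichment relative to the planted anchors.
* The TAD classifier reports boundary/gap/straddling ends as unassigned;
  percentages over "assigned" interactions are therefore conditional.
* `ld_expand` assumes a pre-pooled phased panel; population pooling is
  the caller's responsibility.
* The GO machinery handles is_a edges only; part_of and regulates
  relations are out of scope, as is any ontology download.
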