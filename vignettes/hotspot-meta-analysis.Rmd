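---
title: "Calling QTL/QTN clusters and consensus hotspots for maize kernel size"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling QTL/QTN clusters and consensus hotspots for maize kernel size}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kernelhotspots)
library(dplyr)
```

## The problem

Hundreds of linkage-mapping studies and genome-wide association studies
have reported quantitative trait loci (QTLs) and quantitative trait
nucleotides (QTNs) for the four maize kernel size traits — kernel length
(KL), kernel width (KW), kernel thickness (KT) and hundred-kernel weight
(HKW). Individually these signals are noisy: populations, environments and
marker systems differ between studies, and most reported intervals are too
wide to nominate genes. Where many independent signals pile up on the same
stretch of the B73_V4 reference genome, however, the region becomes a
credible target for fine mapping. This package implements that
meta-analysis: it places literature QTLs on the physical map, calls
trait-specific QTL and QTN clusters, merges clusters of all traits into
consensus *hotspots*, co-locates cloned genes, and screens hotspot genes by
kernel expression and GO over-representation.

## The rules and their parameters

All co-localization logic operates on 1-based, inclusive nucleotide
coordinates on B73_V4 (`b73_v4_build()`), the convention in which published
hotspot spans are printed; BED output converts to 0-based half-open.

**Projection.** A literature QTL has no physical coordinates of its own; it
is delimited by two flanking genetic markers. `project_qtls()` looks both
markers up in a physical marker map and spans the interval between them.
Records are rejected — not dropped silently — when a marker name is absent
(`missing-marker`), unknown to the map (`unmapped-marker`), or when the
markers sit on different chromosomes (`cross-chromosome`). Genetic-map
orientation often disagrees with the physical map, so reversed marker pairs
are swapped silently, and two identical positions give a 1-nt interval
rather than a rejection. No interpolation from centimorgan positions is
attempted, and projected spans are not trimmed by reported confidence
intervals: the flanking-marker span is the unit of clustering.

**QTL clusters.** A region where at least 3 projected QTLs of one trait
co-localize (`find_qtl_clusters()`, `min_members = 3`). "Co-localized" is
interpreted as connected components of the pairwise-overlap graph — the
behaviour of `bedtools merge` at distance 0 — so overlap chains
transitively, and intervals that merely touch (`end + 1 == start`) are not
merged. The cluster span is the union extent of its members, which is why
published cluster spans can far exceed any single QTL. Clustering is
per-trait: one region may host clusters of several traits. No maximum
cluster width is imposed; long merge chains are reported as-is.

**QTN clusters.** A region where a 5 Mb sliding window holds at least 5
QTNs of one trait (`find_qtn_clusters()`, `window = 5e6`, `min_count = 5`).
The window has no natural stride, so windows are anchored at the QTN
positions themselves — a window boundary only matters at a data point, so
this is equivalent to a 1-nt stride. Containment is inclusive
(`last - first <= window`). Overlapping qualifying windows are chained, and
the reported span is trimmed to the extremal member positions; chained
clusters may therefore exceed one window length, as published QTN-cluster
spans do. We require the density rule per qualifying window before
chaining, not in every sub-window of the chained region.

**Naming.** Clusters are named `Trait-qCL<chr>-<i>` (QTL) and
`Trait-gCL<chr>-<i>` (QTN), the field convention; the index restarts at 1
per trait per chromosome in start order, so the second KW QTL cluster on
chromosome 1 is `KW-qCL1-2`. Naming is deterministic.

**Hotspots.** Clusters of all four traits and both kinds are pooled;
connected components of cluster overlap with at least 3 members become
hotspots (`integrate_hotspots()`, `min_clusters = 3`), numbered `HS01`,
`HS02`, ... genome-wide by (chromosome, start). The hotspot extent is the
union span of its members. Component semantics (a connected chain) rather
than clique semantics (a common intersection point) is used; the published
member lists are consistent with components, and the choice is surfaced
here because the rule is not otherwise pinned down. Cloned genes are
co-located by any-overlap (at least 1 nt), the least arbitrary containment
rule; genes recorded without base-pair coordinates are skipped with a
warning.

**Candidate screening.** For genes in hotspots, `expression_summary()`
computes MaxExp (maximal FPKM over all tissues) and MaxExpKernel (over a
configurable kernel-tissue set); `filter_candidates()` passes genes with
MaxExpKernel >= 50 FPKM and MaxExp/MaxExpKernel <= 3, both bounds
inclusive. Which tissues count as "kernel" differs between expression
atlases, so the set is an explicit argument rather than a constant.
`bin_expression()` reports the standard histograms; the extreme classes
are strict (`>500`, `<10`), which forces lower-inclusive internal bins
(`[10, 20)`, ..., `[100, 200)`) with 500 itself kept in `200-500`.
PPR genes are found by a case-insensitive match of "pentatricopeptide" or
the standalone token "PPR"; token boundaries prevent substring hits such as
"su**ppr**essor".

**GO enrichment.** `enrich_go()` tests each term by the one-sided
hypergeometric (upper tail, via the stats distribution functions) and
adjusts across tested terms by Benjamini–Hochberg, significance at
FDR <= 0.05 — the standard over-representation analysis; the background
defaults to all annotated genes and is configurable. GO-graph propagation
is not performed: the annotation table is taken as given.

## A worked example on synthetic data

The generator plants hotspot loci whose clusters are recoverable by
construction: all QTLs of a planted cluster contain the locus center
(log-normal half-widths, median 2.5 Mb, capped at 8 Mb), planted QTNs sit
within one window of the center, and loci are separated by at least 20 Mb
plus the maximal cluster reach, so planted structure can never chain across
loci. Background records are rejection-sampled outside those exclusion
zones. That separation is the recoverability condition: with it, and no
noise, precision and recall of cluster and hotspot calls are exactly 1.

```{r example}
sim <- simulate_kernel_dataset(seed = 1, background_qtls = 0,
                               background_qtns = 0, missing_marker_rate = 0)
run <- run_kernel_analysis(qtl = sim$qtl, markers = sim$markers,
                           qtn = sim$qtn, genes = sim$genes,
                           expression = sim$expression,
                           kernel_tissues = sim$kernel_tissues,
                           go_annotations = sim$go_annotations)
glance(run)
tidy(run)
recovery_report(run$hotspots, sim$truth$hotspots)
```

```{r plot, fig.width = 7, fig.height = 4}
autoplot(run)
```

### What the simulator does and does not emulate

It reproduces the *statistical shape* the analysis assumes — dense
co-localized signal over sparse background, a realistic share of
unprojectable QTLs (default 25%, mirroring the literature), expression
profiles with known pass/fail labels, and one GO term enriched among
passing genes. It does not emulate linkage disequilibrium, allele
frequencies, effect sizes, population structure or study-specific interval
widths; none of these enter the co-localization rules, so passing tests
demonstrate the rules are implemented correctly, not that real curation
noise behaves like the synthetic background. The published headline counts
(e.g. 187 QTL clusters or 84 QTN clusters genome-wide) depend on the
original curated collections, which are not redistributable here; the
bundled tables of 132 cloned genes and 31 published hotspots are the
in-package anchors instead.

## Reporting on the published hotspot table

```{r fixture}
report_hotspot_fixture()
```

The summary reproduces the published structure exactly: 31 hotspots, seven
on chromosome 1 and none on chromosome 6, 12 with five or more member
clusters, 10 carrying at least one cloned gene, and member counts ranging
3–14. Span arithmetic follows the printed convention
`(end - start) / 1e6`, rounded half-up:

```{r spans}
span_mb(20505000, 52520534, 0)   # HS02, 32 Mb
span_mb(20505000, 69017291, 1)   # widest QTL-cluster region, 48.5 Mb
```

## Numerical and degenerate-input choices

* Interval validation admits exactly `1 <= start <= end <= chromosome
  length`; zero-width (1-nt) intervals are legal everywhere.
* Sweep-line merging is O(n log n) and is equivalence-tested against an
  O(n^2) pairwise-overlap graph oracle on random instances up to n = 500.
* The QTN rule is equivalence-tested against exhaustive anchored-window
  enumeration; the hypergeometric tail against exhaustive subset
  enumeration for backgrounds up to 12 genes; BH against the hand formula
  `min_{j >= i} p_(j) m / j`.
* Ties in cluster ordering are broken by (chromosome order in the build,
  start, trait), making names and hotspot numbers reproducible
  byte-for-byte across runs.
* Test and recovery problem sizes (hundreds of intervals, 20 simulation
  seeds, 60–200 genes) were chosen so the whole suite exercises every rule
  at full strength while remaining quick to run on a laptop.

## Limitations

* Component (chain) semantics for "co-localized" is a modelling choice;
  a clique rule would give narrower hotspots. The choice is configurable
  only by post-filtering, not by an argument.
* Whether chained QTN regions must satisfy the density rule in *every*
  window cannot be settled from published descriptions; we require it per
  qualifying window before chaining.
* Genes recorded without coordinates cannot be co-located and are skipped
  (with a warning), so gene counts per hotspot are lower bounds when the
  gene table is chromosome-only.
* GO results depend entirely on the annotation table supplied; no
  ontology-graph ancestor propagation is applied.
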