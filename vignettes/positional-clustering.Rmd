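---
title: "Positional clustering of co-expressed genes: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Positional clustering of co-expressed genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(posclust)
```

## The problem

Eukaryotic genes are not randomly placed: functionally linked, co-expressed
genes are often found in physical proximity, in operon-like neighborhoods
whose co-regulation persists regardless of strand orientation. Given (a) a
table of gene coordinates as exported from a genome database such as Biomart
and (b) one or more expression values per gene from any assay on a common
scale, `posclust` selects genes by expression and groups the selected genes
into *positional clusters* — runs of two or more genes on one chromosome in
which every consecutive pair of gene starts lies within a distance
threshold.

## The clustering rule and its assumptions

Each chromosome is processed separately, genes in non-decreasing start
order. Gene *i* belongs to the cluster of gene *i−1* iff
`start(i) − start(i−1) ≤ D`; otherwise it opens a new cluster. Single-gene
clusters are eliminated during the traversal. Identifiers are assigned
progressively across the whole run (1, 2, …), chromosomes taken in order of
first appearance in the input, so identifiers are unique within a CLU file.

Assumptions worth being explicit about:

* **Start-to-start distance.** Gene length is ignored: a long gene whose
  end lies near its neighbor's start does not chain unless the starts are
  within `D`. This is a deliberate modeling simplification — one distance,
  easy to reason about — not an oversight; it is also why the rule is
  exactly single-linkage clustering of the start coordinates cut at `D`
  (the test suite checks this equivalence against `stats::hclust` on
  thousands of random instances).
* **Strand-agnostic.** Transcriptional neighborhood effects are reported on
  both orientations, so strand never enters the distance. Strand-specific
  analyses are done by pre-filtering the input to one strand.
* **Expression never affects membership.** Expression selects which genes
  enter the table (`filter_by_expression()`); after that, clustering is
  purely positional.
* **A single global threshold.** Gene density varies along real
  chromosomes; a per-region threshold was rejected in favor of a single
  interpretable cutoff. Density differences are explored by re-running at
  several thresholds — `clustered_genes()` grows monotonically with `D`, a
  property the tests enforce.

## Parameters

| parameter | where | units | default | rationale |
|---|---|---|---|---|
| `threshold_bp` (D) | `pos_cluster()` | bp | none (required) | choose from mean gene density; ~20 kbp for a mosquito-sized genome |
| `threshold`, `indices`, `combine`, `direction` | `filter_spec()` | expression scale | all indices, `any`, `keep_ge` | both up- and down-regulated selections are common, so both directions are exposed; comparison is inclusive (`>=`/`<=`), and `NaN` fails every test |
| `n`, `runs`, `seed` | `random_clustering_runs()` | genes, count | none | `n` must equal the size of the observed gene set for the null to be comparable; 20 runs is a practical minimum for the t-test |
| `min_diameter`, `max_diameter`, `scaling` | `view_style()` | drawing units | 4, 24, `sqrt` | see "Numerical choices" |

## The file formats

The on-disk exchange formats are deliberately trivial text:

* **GDF** (gene data file): one gene per line, fields
  `dset genename chrom start end strand expr1 … exprK`, whitespace
  delimited, missing expression written as the literal token `NaN`. The
  `dset` label records which input dataset a gene came from, which matters
  when clusters are updated iteratively with genes from other sources.
* **CLU** (cluster file): header `nClusters N`, then each cluster as its
  id, `beginCluster`, one member line per gene —
  `dset genename chrom strand start stop exp1 …` (note strand precedes
  start here, unlike GDF) — and `endCluster`.
* The random-baseline summary: one row per run,
  `run n.clusts n.tot.clust.genes n.genes per cluster`, sizes
  space-separated.

Both structured formats round-trip bit-exactly (numbers are serialized with
up to 17 significant digits), and readers report 1-based line numbers on
malformed input. Lines beginning with `#` are skipped — an extension of the
original formats, harmless because neither format uses `#`.

## The significance baseline

To ask whether an observed clustering is more than what gene density alone
produces, `random_clustering_runs()` draws `n` genes uniformly *without
replacement* from a pool GDF (sampling a gene *set*; with-replacement draws
would create duplicate names the data model forbids), clusters each draw at
the same `D`, and summarizes each run. `compare_observed_vs_random()` then
runs a one-sample Student's t-test with the random runs as the sample and
the observed statistic as the hypothesized mean — the observed value is a
single number, not a sample, so a one-sample design is the appropriate one.
The t statistic is `(mean − mu)/(sd/√k)` with `k−1` degrees of freedom,
two-sided.

Edge cases: if all random runs give the identical value the test is
degenerate (zero variance) and a flagged report is returned instead of a t
statistic, stating whether the observed value lies outside the random
support; runs with zero clusters have no mean cluster size and are dropped
from that statistic with a warning. `one_sample_t_test()` itself throws on
zero variance.

One RNG seed controls the whole batch; per-run sub-seeds are derived from
it, so run `r` is reproducible independently of how many runs surround it.

## What the synthetic generator emulates — and what it does not

`generate_synthetic()` builds the stated world the tests run in: four
chromosome arms of 42–61 Mbp (mosquito-like), two planted clusters per arm
(3 and 4 genes) with intra-cluster start gaps of 2–10 kbp, isolated
background genes at least 50 kbp from everything, five expression
conditions in which each planted cluster shares one "hot" condition
(mean 8 over background mean 1, emulating a stage-specific hot-spot), and
an optional fraction of missing cells. Groups are laid out sequentially in
random order with at least the isolation gap between them, so by
construction any threshold between the largest intra-cluster gap and the
smallest isolation gap recovers exactly the planted clusters.

This means a green recovery test establishes that the algorithm finds
clusters whose geometry is unambiguous. It does **not** establish behavior
on real genomes, where gene density varies continuously and "cluster" is a
threshold-dependent judgment; nor does the expression model capture
microarray noise structure, probe effects, or correlated replicates. The
published whole-genome cluster counts for real datasets depend on external
expression data and a specific genome-coordinate release and are therefore
out of the package's test scope; what the tests pin down instead are the
algorithmic properties (oracle equivalence, monotonicity, limit cases,
format fidelity) that any such analysis relies on.

## Numerical and design choices

* **Coordinates** are 1-based inclusive integers as exported by Biomart and
  are never rescaled. Two genes with identical starts have distance 0 and
  always chain; sorting ties break by end, then name, so results are
  deterministic.
* **Merging** keeps the *first* instance of a duplicated gene name and
  reports the duplicates rather than averaging probes: how to aggregate
  replicates is an analysis decision the package refuses to automate. Genes
  present in only one input table are dropped with a warning. The rule is
  applied identically to both input tables.
* **Filtering** treats `NaN` as failing every comparison, so genes with
  missing values never pass a filter accidentally; `fix_nan()` exists
  precisely to opt such genes back in. Whether the original comparison was
  strict or inclusive is not documented anywhere authoritative; `>=` was
  chosen and is stated in the function documentation.
* **Iterative updating** (`add_genes()`/`update()`) re-clusters the union
  of the current members and the new genes and renumbers identifiers; this
  keeps the "same rules as the initial run" guarantee exact. Genes
  discarded as singletons in the original run are gone from the CLU and are
  not resurrected — an information-loss property inherited from the
  file-based workflow; rerun `pos_cluster()` on merged GDFs to avoid it. A
  threshold differing from the original one warns but is allowed.
* **Glyph scaling** in the views defaults to `sqrt`, making glyph *area*
  (not diameter) proportional to the encoded magnitude — "proportional" is
  ambiguous between the two, and area is the perceptually honest choice;
  `linear` is available. Zero expression maps to zero diameter (a point),
  `NaN` to a hollow point distinguishable from a true zero, and negative
  values (down-regulation log-ratios) to a point with a warning since
  negative diameters have no meaning. In the multiple-cluster view, all
  chromosomes share one bp-to-unit scale factor, so drawn line lengths
  reflect relative spans; the cluster position label is the kbp of the
  first gene's start. No label collision avoidance is attempted — labels
  are separate editable SVG text nodes, matching the manual-adjustment
  workflow the figures are meant for.
* **CLU reading** attaches `threshold_bp = NA` unless the caller supplies
  it: the file format does not record the threshold.

## Known limitations

* The start-distance rule can split biologically contiguous arrangements
  when a very long gene separates two otherwise-close starts.
* The baseline t-test compares one summary statistic at a time; it does not
  assess the significance of individual clusters against local gene
  density (a per-cluster test would be a natural extension).
* Two-gene clusters may be local duplication artifacts; the size
  distribution exposes the ≥3 and ≥4 breakdowns so analyses can discount
  them, but the package does not judge.
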