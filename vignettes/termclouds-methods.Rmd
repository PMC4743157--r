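---
title: "Methods behind termclouds: enrichment, filtering and cloud layout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind termclouds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(termclouds)
```

This vignette records the statistical model, the numerical choices and the
design decisions behind the package, in the order data flows through it.

## The over-representation model

A query list is tested against an annotation set whose universe defaults to
the union of all annotated genes — the implicit background of the common
enrichment services; pass a universe explicitly for platform-specific
backgrounds (the genes actually measured on an array, say). Gene
identifiers are opaque, case-sensitive strings: no identifier conversion is
attempted, but `apply_gene_map()` lets a two-column mapping be applied as a
preprocessing step.

Each term with overlap $k \ge 1$ is scored with the one-sided
hypergeometric tail $P(X \ge k)$, evaluated through the log-scale tail of
`phyper` so that extreme p-values keep full relative accuracy; an exact
underflow to zero is clamped to the smallest positive double so
$-\log_{10} p$ stays finite. Benjamini–Hochberg correction is applied with
$m$ = the number of terms actually tested, i.e. those with $k \ge 1$; terms
with no overlap carry no evidence in either direction and are not counted.
BH with the default $\alpha = 0.05$ is a deliberate, reproducible choice of
an offline multiplicity correction; results computed upstream by other
tools keep their own correction when imported through
`parse_term_table()`, whose p-values are taken as already adjusted.

Ties in $p$ are broken by larger term size, then lexicographic term id, so
every ranking the package produces is fully deterministic.

## The display filter

The pipeline order is sources → size window → hierarchy → cap, and each
stage only removes rows, so the composition is idempotent. The cap runs
last deliberately: it is meant to bound what is *displayed*, so it must act
on the post-redundancy list. Defaults: terms with more than 50 and fewer
than 1000 genes (both bounds strict), sources BP/KEGG/REAC, at most 30
terms. Rows imported without a size or source column are exempt from the
corresponding filter rather than silently dropped — emptied results from a
perfectly valid upstream table would otherwise be a confusing failure mode.

"Related terms" is read as sharing at least one **direct** parent, with the
direct parent–child relation itself also grouping; groups are the connected
components of that graph and each keeps its most significant member. Direct
parentage is the default because it is computable from a plain edge list
without the ancestor closure and keeps groups tight; grouping over the full
ancestor closure is available via `relation = "ancestor"` for ontologies
where sibling terms rarely share a direct parent. Only `is_a` edges are
read from OBO input; `part_of` and `regulates` change the semantics of
"parent" and are intentionally out of scope.

## Word clouds

The display weight of a term is $-\log_{10} p_{\mathrm{adj}}$, capped at 16
(i.e. $p = 10^{-16}$) so a single extreme p-value cannot flatten every
other word into illegibility. Within one cloud, font sizes are proportional
to weights and scaled so the heaviest word gets 20 pt before packing; this
per-cloud rescaling is what makes font sizes *incomparable between clouds*,
so a second channel carries the absolute signal: one affine map, computed
over all clouds of the figure at once, takes the figure-wide weight range
onto gray levels $[0.65, 0]$. The lightest gray is 0.65 rather than 1 so
the weakest displayed term is still readable; a degenerate weight range
(all weights equal) maps everything to black.

Placement is greedy, heaviest word first. A word's box is estimated as
$0.55 \cdot \mathrm{size} \cdot \mathrm{nchar}$ wide and
$1.1 \cdot \mathrm{size}$ tall; candidate centres are scanned on an outward
rectangular spiral from the canvas centre, and elongated boxes (aspect
ratio above 2.5) order candidates by vertical offset first, which makes
long multi-word phrases tile into horizontal bands instead of fighting for
the centre. Phrases are never split, rotated or elided — a term name is only
useful intact. If any word finds no collision-free position, *all* font
sizes are multiplied by 0.95 and the layout restarts, so size ratios (and
therefore the weight ordering of sizes) survive any number of shrink
iterations exactly. A single word that cannot fit the canvas even at the
4 pt minimum font is a hard error naming the word. The algorithm uses no
randomness at all: identical input gives byte-identical layouts, which is
what makes SVG regression testing by text diff possible.

## Producers

**Clusters.** One block per cluster id, members as a single gene list, and
per-sample boxplots over the members' expression rows. Boxplot statistics
follow the Tukey convention — quartiles by linear interpolation (`quantile`
type 7), whiskers at the most extreme observation within 1.5 IQR — since no
single convention is universal and this is the one base R's
`boxplot`-reading audience expects.

**Differential expression.** Per contrast, up ($\mathrm{effect} > 0$) and
down ($\mathrm{effect} < 0$) lists at the adjusted-p threshold; an effect of
exactly 0 joins neither side. Empty sides still render, annotated
"0 genes", so a null contrast remains visible in the figure rather than
silently vanishing.

**PCA.** Samples are observations, genes variables; the matrix is centred
per gene, not variance-scaled by default — expression inputs are assumed
log-scale, where per-gene scaling would inflate flat genes (a `scale.` flag
enables it). Each component's sign is fixed so its largest-magnitude
loading is positive: a PC's sign is arbitrary, and a convention makes
outputs reproducible across BLAS implementations. Per component the 500
largest positive and 500 largest negative loadings form the two gene lists
(a loading of exactly 0 joins neither); the panel is a stacked histogram of
the scores with shared bin edges (bin count by Sturges' rule on the pooled
scores, classes stacked in first-appearance order), annotated with the
percent variance explained.

**PCoA.** Bray–Curtis dissimilarity, with the degenerate all-zero sample
pair defined as distance 0 (with a warning) rather than NaN; classical
Gower double-centering; axes with negative eigenvalues are dropped with a
magnitude summary. Because PCoA has no loadings, features are tied to axes
by the Spearman correlation of abundance with axis coordinates. The test
p-value is an exact two-sided permutation p for $n \le 8$ samples
(enumeration of all $n!$ orderings, valid under ties) and the usual
t-approximation above — exact where it is cheap, standard elsewhere. BH runs
across features *within* each axis, and the clouds are built directly from
feature names weighted by $-\log_{10} p_{\mathrm{adj}}$; no enrichment step
is involved. At least 4 samples are required; below that the permutation
distribution is too coarse to mean anything.

## Rendering

Blocks stack vertically; figure height is exactly linear in the block
count. The default block width (800 pt) and heights put 5–6 blocks on a
portrait page. Two-cloud blocks place the negative/down cloud left and the
positive/up cloud right. Grays are computed figure-wide *before* any cloud
is placed. The SVG backend writes the scene itself with fixed 3-decimal
coordinate formatting, which is why output is byte-stable; PDF and PNG go
through the standard graphics devices and inherit their font handling. The
intermediate model file is versioned JSON written at 17 significant
digits, so a write/read round trip reproduces every double bit-exactly.

## Synthetic data

The generators exist so that every stage is testable offline, and their
defaults are fixed study conditions, not tuning knobs.

- `make_annotation()`: 100 terms over 5000 genes in a 3-layer tree; term
  sizes log-uniform in $[5, 2000]$ — chosen to straddle the (50, 1000)
  display window from both sides so the size filter is exercised
  non-trivially — children's gene sets nested in their parent's, and 2–5
  word term names to exercise long-phrase packing.
- `make_expression()`: five distinct smooth temporal profiles (sigmoidal
  switches, transient peaks, a dip) over nine time points, Gaussian noise
  at half the within-profile amplitude; the noiseless limit is exactly
  recoverable by nearest-profile assignment.
- `make_planted_expression()`: two classes separated along one latent
  direction through 400 shifted genes out of 2000 — the recovery fixture
  for the PCA gene lists.
- `make_abundance()`: Dirichlet-multinomial counts, three habitats, five
  planted taxa per habitat boosted 20-fold, sequencing depth 10000 — a
  strongly structured, body-site-like community table.

What these fixtures do **not** emulate: correlated gene co-expression
beyond cluster membership, compositional effects of normalisation,
batch structure, overdispersion beyond the Dirichlet-multinomial, or the
dependence structure of real GO (where a term's siblings overlap without
sharing all genes). Passing the recovery and type-I checks therefore shows
the machinery is correct under its stated model, not that any particular
real dataset will behave as cleanly.

## Problem sizes and limitations

The test and acceptance workloads use 100–120 term annotations over a few
thousand genes, 500-replicate Monte-Carlo loops, and exhaustive
hypergeometric enumeration up to $N = 60$ — sizes at which the exhaustive
oracles are exact and fast. Known limitations: the hierarchy filter's
direct-parent reading can under-group ontologies whose related siblings
only meet at grandparent level (use `relation = "ancestor"`); box-size
estimation uses a fixed per-character width, so proportional-font renderers
may show more inter-word whitespace than the layout's conservative boxes
imply; and the t-approximation for Spearman p at moderate $n$ is known to
be slightly anti-conservative in the extreme tails.
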