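---
title: "Dual-condition signed co-expression networks and differential correlation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-condition signed co-expression networks and differential correlation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexdiff)
```

## The problem

Contrasting cultivars of a crop — here the motivating case is salt-sensitive
versus salt-tolerant rice — can respond to the same stress with different
gene-regulatory wiring rather than merely different expression levels. Two
complementary signals capture this rewiring:

1. **Centrality shifts.** A gene that is a hub of the co-expression network
   in one cultivar group but peripheral (or absent) in the other points to
   condition-specific regulation.
2. **Differential correlation.** A gene pair strongly co-expressed in one
   group and uncorrelated in the other marks an interaction gained or lost
   with the phenotype, even when neither gene changes its own level.

`coexdiff` implements the full pipeline around these two signals: data
preparation, signed weighted network construction, centrality screening,
the Fisher z differential-correlation test with FDR control, and the
annotation layer (GO over-representation, marker-interval overlap, and
transcription-factor-centred differential modules). A synthetic-data
generator with planted truth makes every stage testable without external
data.

## Preprocessing model

Expression tables arrive as genes-by-samples tibbles, one or several per
condition group. The preparation steps run in a fixed order:

1. **Probe averaging** — microarray probe rows mapping to one gene are
   averaged per sample (`average_probes()`); rows absent from the probe map
   are taken to be gene-level already, so RNA-seq tables pass through.
2. **Merging** — datasets of a group are reduced to the genes present in
   every dataset, keeping the first input's gene order
   (`merge_datasets()`).
3. **Rescaling** — each sample is min-max rescaled to 0–100
   (`rescale_samples()`), making a single expression floor meaningful
   across platforms.
4. **Filtering** — a gene is kept when its value exceeds 1 (on the 0–100
   scale) in at least 50% of samples (`filter_low_expression()`). The
   boundary is inclusive: exactly half the samples suffices. Both knobs are
   arguments.
5. **Outlier removal** — samples are clustered by average linkage on
   Euclidean distance (`detect_outlier_samples()`); cutting the tree keeps
   the largest cluster. No principled universal cut height exists, so the
   default is an automatic 1.5 × median merge height, and real analyses
   should override it after looking at the dendrogram (`cut_height`
   argument).

## Network model

For each group the pipeline computes, in order (`build_network()` chains
them):

* Pearson correlation `r` between all gene pairs (`correlation_matrix()`);
* the **signed similarity** `s = (1 + r) / 2`, mapping r = −1, 0, 1 to
  s = 0, 0.5, 1 — strong negative correlation means *unconnected*, which
  preserves the sign information a plain `|r|` network discards
  (`signed_similarity()`);
* the **soft-threshold adjacency** `a = s^β` (`soft_adjacency()`);
* the **signed topological overlap**
  `TOM_ij = (a_ij + Σ_{u≠i,j} a_iu a_uj) / (min(k_i, k_j) + 1 − a_ij)`,
  with connectivity `k_i = Σ_{u≠i} a_ui`, which rewards shared
  neighbourhoods over single strong edges (`signed_tom()`);
* thresholded **edge export** at `TOM ≥ 0.4` (`export_edges()`); a gene
  belongs to the network only if it keeps at least one edge.

### Choosing the power β

`pick_soft_threshold()` scores each candidate power by the scale-free model
fit of the resulting connectivity distribution: connectivities are split
into 10 equal-width bins, and `log10(frequency)` is regressed on
`log10(mean k)` per bin; the signed R² (negated for a positive slope) is
the fit index, and the smallest candidate reaching R² ≥ 0.5 is selected.
Binning is on the raw connectivity scale, matching the behaviour of the
standard selector used in this field; the weakly connected bulk then
occupies the first bins and the decreasing tail drives the fit. Degenerate
one-point distributions report R² = 0 with a warning rather than an error.

Two numerical regimes matter and are worth stating plainly:

* With the conventional high power for signed networks (β = 22, available
  as `beta = 22` everywhere), only pairs with `r ≳ 0.93` survive the 0.4
  TOM cutoff. This is the regime the cutoff is calibrated for.
* With a low automatically selected power (β ≈ 4–8 on the bundled
  fixtures) the TOM of even a perfectly correlated pair is diluted by the
  many moderate connections in its denominator, and the 0.4 cutoff can
  yield an empty network. `run_pipeline()` warns and continues with empty
  centrality tables in that case instead of failing the run. Users pairing
  `beta = "auto"` with edge export should lower `tom_cutoff` accordingly.

### Centrality screens

Centralities are computed on the unweighted graph induced by the exported
edges (`compute_centralities()`), matching the conventions of the usual
interactive network analyzers: degree DG; betweenness BW normalised by
`(N−1)(N−2)/2` over the whole graph even when disconnected; closeness CN
defined as the reciprocal mean shortest path to *reachable* nodes (so a
node adjacent to its whole component scores exactly 1, and an isolated
node 0); and the local clustering coefficient CC. The screens are
inclusive: high-degree means `DG ≥ 0.5 (N−1)`, high-closeness means
`CN ≥ 0.75`. `cross_network_comparison()` reports genes high in either
network with the value 0 for genes absent from the other network, and
flags genes present but weakly connected there (`DG ≤ 10%` of other genes,
or `CN ≤ 0.5`).

## Differential correlation

For every unordered pair over the genes shared by both groups
(`screen_all_pairs()`), the group correlations `r_s`, `r_t` are compared
with Fisher's z-test:

`z = (atanh(r_s) − atanh(r_t)) / sqrt(1/(n_s − 3) + 1/(n_t − 3))`,

two-sided normal p-value, with `|r|` clamped at `1 − 1e-7` before the
transform so perfect correlations stay finite. The screen tests *all*
shared-gene pairs, not only exported edges: a pair can be differential
without either gene being a hub.

Selection (`select_significant_pairs()`) requires both
`|Δr| = |r_s − r_t| ≥ 0.7` and `FDR ≤ 0.05` (both inclusive). The Δr floor
exists to exclude differences between two unremarkable correlations — for
example `r_s = 0` versus `r_t = 0.6` is never reported, however
significant.

Two FDR methods are available (`adjust_fdr()`): Benjamini–Hochberg (the
default — deterministic, conservative, no tuning) and an Efron-style
**local fdr** for fidelity with empirical-null practice: the z histogram
(120 bins) gets a Poisson natural-spline fit for the marginal density
`f(z)`; a quadratic log-density fit to the central 25–75% quantile mass
yields the empirical null `N(μ₀, σ₀²)` and null proportion π₀ by central
matching; each pair reports `fdr(z) = π₀ f₀(z)/f(z)`, capped at 1. When
the central mass is not peaked the estimator falls back to the theoretical
N(0, 1) null.

## Annotation layer

* **GO over-representation** (`go_enrichment()`): one-sided Fisher exact
  test, computed as the hypergeometric upper tail on the 2×2 table of
  study/background × term/no-term, BH-adjusted across tested terms, and
  reported at `p ≤ 0.05` and `FDR ≤ 0.05`. The annotation is a flat
  gene-to-term table; propagation up the ontology graph is deliberately
  not performed (the flat table is reproducible; propagated results depend
  on an ontology release) — a documented limitation.
* **Marker-interval mapping** (`map_genes_to_intervals()`): a gene,
  represented by one coordinate, hits an interval when it lies inside the
  closed 1-based range on the same chromosome. Both boundaries inclusive.
* **Transcription factors** (`select_transcription_factors()`): genes
  annotated to any of the four transcription-activity GO terms
  (GO:0006350, GO:0030528, GO:0006351, GO:0006366; configurable), taken
  from the high-centrality gene lists.
* **TF modules** (`build_tf_modules()`): each TF with at least one
  selected differential pair becomes a module of its partners; the sign
  label is *positive* when the pair is more strongly correlated in the
  sensitive group and *negative* otherwise. Module edges are by
  construction a subset of the selected pairs.

`run_pipeline()` chains all stages, returns every intermediate table, and
optionally writes them as sorted TSVs plus a JSON manifest (configuration
hash, package version, seed, per-stage counts); a rerun under the same
configuration is byte-identical.

## The synthetic-data generator

`simulate_two_group_expression()` draws both groups from a latent factor
model chosen because the pipeline consumes only correlations:

* **Modules.** Each of the 6 default blocks of 25 genes shares a
  unit-variance factor. Membership is *graded*: two core genes load at
  `sqrt(within_module_cor)` (default pairwise core correlation 0.95) and
  the remaining loadings decline cubically to a floor of 30%, with module
  tightness itself declining slightly (0.012 per module). The graded
  profile is the same device the field's standard expression simulators
  use, and it is what gives the connectivity distribution the heavy
  right-skewed shape on which soft-threshold selection is meaningful — a
  flat equal-loading design produces a two-point degree distribution that
  no power can make scale-free.
* **Hubs.** One extra graded block (default 10 genes) whose top members
  carry the highest connectivity.
* **Planted differential pairs.** Disjoint from the blocks; each pair is a
  bivariate draw with correlation `0.05 + planted_delta` in the sensitive
  group (clamped to ±0.99) and `planted_delta` lower in the tolerant
  group. The default Δ = 0.9 therefore plants pairs at r ≈ 0.95 versus
  0.05: strongly co-expressed in one condition — inside the regime that
  survives TOM export at β = 22 — and absent in the other.
* **Noise genes.** The remainder are independent.
* **Transform.** Latent values map to expression by `50 + 10·z`, floored
  at zero. The affine map preserves every planted correlation exactly; the
  floor sits five standard deviations out.

Group sizes default to 72 and 96 samples, the scale of a multi-study merge
after outlier removal. `corrupt_with_probes_and_outliers()` adds duplicate
probe rows and location-shifted outlier samples (default shift: five
expression-scale standard deviations, unambiguous for average-linkage
detection), with truth recorded. `generate_fixture_annotations()` emits a
GO table with one term deliberately packed with the hub genes, the four
transcription GO terms on a known subset (including one side of the first
planted pairs, so TF modules exist end-to-end), positions for every gene,
and intervals covering a recorded subset.

What the generator does *not* emulate: count-distribution noise
(negative-binomial dispersion), batch effects, and correlated residuals
between modules. Passing tests therefore demonstrate the correctness of
the machinery and its statistical calibration under a clean factor model,
not robustness to platform artefacts.

## Numerical choices and edge cases

* Correlations are clipped to `[-1, 1]` after `cor()` to absorb rounding;
  constant gene rows are dropped with a warning (their correlation is
  undefined), and pairs involving them leave the screen.
* The TOM denominator is guarded at `1e-12`; with `a ∈ [0, 1]` it is
  mathematically `≥ 1 − a_ij ≥ 0`. The TOM diagonal is 1 by convention and
  irrelevant to export.
* `scale_free_fit` needs at least 3 occupied bins and a non-degenerate
  connectivity range; otherwise R² = 0 with a warning. If no candidate
  power reaches the target, the best-fitting one is selected with a
  warning rather than failing.
* Fisher's z clamps `|r|` at `1 − 1e-7`; the test refuses groups of 3 or
  fewer samples (its variance term requires n > 3).
* Ties at every selection boundary (degree fraction, closeness floor,
  `|Δr|`, FDR, enrichment p) are kept, matching the inclusive phrasing of
  each rule.
* All writers sort rows lexicographically, so outputs are byte-stable.

## Problem sizes used in the test-suite

The bundled checks run the default 300-gene fixture (6 × 25 module genes,
10 hubs, 10 planted pairs, 72/96 samples), 100-instance oracle sweeps for
TOM and the centralities, 5000 simulated null pairs for the size of the
z-test, and ten 2020-pair replicates for the power/FDR check — sizes at
which each property is statistically identifiable while the whole suite
runs in well under a minute on a laptop. Statistical assertions on
stochastic quantities use tolerances derived from the sampling noise at
those sizes (for example, a planted |Δr| of 0.9 estimated at n = 72/96
has a standard error near 0.11, so per-draw assertions use wider bands
than per-pair means over seeds).

## Known limitations

* Only Pearson correlation and exactly two groups are supported.
* No module detection (dynamic tree cut), eigengenes, or module–trait
  analysis — the pipeline's scope ends at centrality screens and the
  differential-correlation layer.
* GO enrichment ignores ontology structure (no ancestor propagation).
* The local-fdr estimator is a compact central-matching implementation;
  for publication-grade empirical-null analysis a dedicated package
  should be cross-checked.
* Meta-QTL intervals are consumed as supplied, never re-estimated.
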