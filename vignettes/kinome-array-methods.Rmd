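---
title: "Methods: reliability scoring, differential phosphorylation and surface similarity for kinome arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reliability scoring, differential phosphorylation and surface similarity for kinome arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinomeSR)
```

# The measurement and its noise

A tyrosine-kinase peptide array exposes 144 consensus peptide substrates to
a cell lysate; active kinases phosphorylate their substrates and a
fluorescent antibody reports the per-spot signal, three technical
replicates per condition. Two artefacts dominate: background subtraction
can leave small *negative* signals on weak spots, and the replicate
scatter varies enormously between spots. `kinomeSR` deals with the first
by flooring negatives to zero (`floor_negatives()`, applied once and
idempotent) and with the second by a per-spot reliability score that
gates all downstream analysis. One spot is a pre-phosphorylated internal
positive control (the `ART_003` peptide on the tyrosine-kinase chip); it
is excluded before analysis (`exclude_control()`).

The per-replicate scalar is deliberately unconstrained: some labs feed an
endpoint intensity, others the initial-velocity slope from the kinetic
image series. The pipeline consumes *any* per-spot, per-replicate scalar;
all statements below hold on whichever scale the caller provides.

# Spot reliability (SR)

For one spot in one group with replicate values $x_1,\dots,x_n$ ($n \ge
2$), let $A$, $M$ and $sd$ be the mean, median and sample ($n-1$)
standard deviation. Two dimensionless ratios are banded:

* $P_1 = sd/A$, a coefficient of variation: **High** if $P_1 < 0.20$,
  **Medium** if $0.20 \le P_1 < 0.50$, **Low** otherwise.
* $P_2 = A/M$, a skew indicator: **High** if $0.80 < P_2 < 1.20$,
  **Medium** on the surrounding ring $0.70 < P_2 < 1.40$, **Low**
  otherwise.

The pair of levels maps to the integer score $SR$:

| P1 \\ P2 | High | Medium | Low |
|---------|------|--------|-----|
| High    | 6    | 5      | 4   |
| Medium  | 5    | 3      | 2   |
| Low     | 4    | 2      | 1   |

Design choices worth
stating because the published ranges leave them open:

* **Boundaries.** The band definitions are printed as strict
  inequalities only. We resolve boundary points outward: $P_1 = 0.20$ is
  Medium, $P_1 = 0.50$ Low; $P_2 \in \{0.80, 1.20\}$ Medium, $P_2 = 0.70$
  and $1.40$ Low. The High region is strictly inside the Medium region,
  which yields a useful monotonicity: shrinking a spot's replicate
  scatter toward its mean can never lower its SR (tested as a property).
* **Undefined ratios.** After flooring, $A = 0$ (all-zero spot) or
  $M = 0$ (zero median) make a ratio undefined. Such spots are classified
  **Low** with a warning, never an error: an all-zero spot is maximally
  unreliable, and raising a hard error would make routine chips with a
  handful of dead spots unanalysable.
* **$n-1$ denominator.** Whether the original analysis used $n$ or $n-1$
  is unknowable from the text; we use the sample sd (the convention of R's
  `sd` and of spreadsheets). At $n = 3$ the two differ by $\sqrt{3/2}$,
  which can flip borderline P1 levels — a caveat for anyone comparing SR
  histograms across implementations.
* Both ratios are scale-free, so SR is invariant to positive rescaling of
  a spot's replicates (tested as a property).

Pairwise analyses only use spots whose SR equals the chosen level in
*both* groups (`select_common_spots()`), avoiding unbalanced
reliability. SR 6 is the default; lower levels trade reliability for
coverage.

# Quantile normalization

Selected spots of the two groups under comparison are normalized
*jointly* over their $2 \times n$ replicate columns
(`quantile_normalize()`): the $k$-th smallest value of each column is
replaced by the mean of the $k$-th smallest values across columns. Tied
values receive the average of the reference values over the ranks their
tied block occupies. The map is idempotent, equivariant under column
permutation, and leaves within-column rank order unchanged; it is checked
against a sort-average-reassign oracle and, on tie-free input, against
limma's implementation.

Two scope decisions:

* **Joint, not global.** Normalizing the pair's six columns together is
  the choice that makes the two groups directly comparable; normalizing
  each group separately would erase exactly the differences being tested.
* **Background correction = flooring.** No normexp-style background model
  is applied; negative flooring is the only background step. This is
  deliberately minimal — the source analysis names no method.

One property of quantile normalization deserves a warning label: because
it forces *identical* column distributions, a large fraction of truly
changed spots (⪆15% of the selected set, realistic only in tiny spot
sets) makes unchanged spots absorb part of the shift in the opposite
direction, producing compensatory significant calls. At the chip's
natural scale (dozens to hundreds of selected spots, few true changes)
the effect is negligible; the synthetic-recovery tests run at a ≤10% DE
fraction for this reason, and the bundled 40-spot example in the README
shows the effect in miniature.

# Differential phosphorylation

Per common spot, a two-sided two-sample Student's *t*-test with pooled
variance (the Welch test is available via `var_equal = FALSE`) on the
normalized replicates, plus the fold change
$FC = \bar{x}_{test}/\bar{x}_{control}$. A spot is *up* if $p < \alpha$
and $FC > 1$, *down* if $p < \alpha$ and $FC < 1$, *ns* otherwise;
$\alpha = 0.05$ by default. Degenerate inputs are defined rather than
fatal: both sides constant and equal gives $p = 1$; both sides constant
and different gives $p = 0$; a zero control mean makes FC undefined and
the record is excluded with a warning.

**No multiple-testing correction by default.** The convention in this
assay's literature is to report raw $p < 0.05$ per spot (published spot
tables retain values like 0.047); Benjamini–Hochberg is available through
`p_adjust = "BH"` for users who want FDR control. Note the replicates are
*technical*, so $p$-values quantify measurement repeatability, not
biological variability — the published design provides nothing better,
and the package documents rather than hides this.

# The χ similarity statistic

$$\chi^2 = \frac{1}{N}\sum_{i=1}^{N}
  \left(\frac{I_0[i] - I_t[i]}{1 - |\sigma_0[i] - \sigma_t[i]|}\right)^2$$

with $I$, $\sigma$ the per-spot mean and sample sd of normalized
intensities (the same $A$/$sd$ definitions as the reliability module).
Decisions:

* **χ vs χ².** The defining equation is for $\chi^2$ while reported
  values are labelled $\chi$; we report $\sqrt{\chi^2}$ and expose the
  squared value via `squared = TRUE`. On a fixed intensity scale the
  square root also makes the statistic behave like a root-mean-square
  distance: under a uniform mean shift $\delta$ with matched sigmas,
  $\chi = \delta$ exactly.
* **Domain.** $1 - |\sigma_0 - \sigma_t| \le 0$ is possible on raw
  fluorescence scales, where sds are in the thousands.
  `pairwise_similarity()` therefore rescales the pair's normalized
  matrix by its global maximum, putting all values (hence all sds) in
  $[0,1]$ and guaranteeing a positive denominator. `compute_chi()` on
  user-built profiles refuses (with the offending spots named) rather
  than silently producing negative-denominator nonsense. Consequence:
  χ values are only comparable within a common intensity scale, and the
  package's values on any given dataset will differ from numbers computed
  on an undisclosed raw scale by an unknown global factor.
* **A documented contradiction.** The source narrative states that
  χ = 1 means identical biological response; the equation gives χ = 0
  for identical profiles. The implementation follows the equation.
* Pairs use pair-specific common-spot sets (not one three-way
  intersection), matching the pairwise definition; `n_spots_used` in the
  result records each pair's $N$.

χ is purely descriptive: no null distribution or permutation $p$-value is
attached, because none is defined for it in this assay's usage.

# Network comparison

Significant spots plus their predicted kinase interactors form undirected
simple graphs (`build_ppin()`: duplicate/reversed edges collapsed,
self-loops dropped, optional node whitelist kept as isolated vertices
when unconnected). Conventions, chosen to match the Cytoscape
NetworkAnalyzer defaults because that is the tool this analysis is
interchanged with:

* degree = incident edge count;
* betweenness = shortest-path betweenness, endpoints excluded, normalized
  by $(n-1)(n-2)/2$;
* closeness, per connected component = (number of reachable nodes) /
  (sum of distances to them); isolated nodes get 0.

The implementation is backed by igraph, but the conventions are verified
exhaustively against a from-scratch BFS oracle on **all** labelled graphs
with ≤ 6 nodes (33,841 graphs) in the acceptance suite. "Upper 10th
percentile" node sets use the linearly interpolated 90th percentile
(`quantile` type 7) with ties included above the threshold — stated
explicitly because the phrase admits several conventions.
`export_networkin_input()` emits one (accession, site) row per
phospho-position of each significant spot, the substrate layout consumed
by sequence-based kinase-site predictors; the predictor itself, STRING's
scoring, module clustering and enrichment are external tools that the
package interfaces with but does not re-implement.

# The synthetic generator: what it emulates, what it does not

`generate_dataset()` produces the stated world the tests run in: 144
spots (one control) × 3 technical replicates per group, log-normal
signals (positive, right-skewed — the natural first model for
fluorescence; the source gives none) around a per-spot baseline shared
across groups (log-sd 1 of spot-to-spot heterogeneity, baseline log-mean
$\log 300$ — mid-range fluorescence counts), multiplicative group fold
effects on chosen spots, and a 2% chance per value of a small negative
replacement emulating background over-subtraction (a sign flip at
1–10% magnitude: the simplest mechanism that exercises the flooring
rule, not a physical background model).

Quality classes are parameterized by their coefficient of variation
because, for a log-normal at small CV, the sample $P_1 \approx$ CV and
$P_2 \approx 1$ — so P1-band membership (hence target SR) is controlled
analytically. Defaults: CV 0.08 (targets SR 6), 0.32 (SR 5), 0.85
(SR 4), mixed 40/35/25%; the sdlog is $\sqrt{\log(1+CV^2)}$ so the true
CV equals the class CV at any magnitude. At CV 0.85 the realized SR
scatters across the lower levels — as real bad spots do.

What a green test does **not** establish: the generator has no spatial
artefacts (gradients, scratches), no kinetic time-series structure, no
correlation between spots beyond the shared baseline, and technical —
not biological — replication. Recovery results therefore validate the
*computational chain* (selection, normalization, testing, χ), not the
biological power of any particular chip experiment.

Fixed-seed simulations in the acceptance suite verify: type-I error at
$\alpha = 0.05$ within 3 binomial SEs over >2000 null spots; ≥90% recall
of injected 0.5-fold effects at CV ≤ 0.1 and $n = 3$ with no injected
spot called up; ≥95% SR-6 recovery at the design CV; and χ within 5% of
an injected uniform shift δ. These thresholds were set from the stated
design, not tuned to the implementation.

# Numerical and reproducibility notes

* The analysis path contains no randomness: identical inputs and
  configuration give byte-identical report files (tested).
  `run_pipeline()` writes a JSON manifest with the configuration, stage
  spot counts and input file hashes.
* Oracle comparisons use 1e-10–1e-12 tolerances; symmetry of χ and of the
  SR table are exact (`identical`), not approximate.
* Missing replicate values are rejected at ingest — every statistic here
  assumes a full replicate vector and no principled imputation rule
  exists for $n = 3$.
* Known limitation: with technical replicates and $n = 3$ per side, the
  *t*-test has 4 degrees of freedom; borderline calls are fragile to a
  single replicate. The SR gate exists precisely to keep such spots out
  at level 6.
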