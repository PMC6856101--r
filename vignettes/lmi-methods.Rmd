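---
title: "Scoring differentiation state with the Lineage Maturation Index"
author: "lmindex authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring differentiation state with the Lineage Maturation Index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lmindex)
```

## The model

Differentiation therapy aims to push malignant cells — classically acute
promyelocytic leukemia blasts under ATRA — along their normal maturation
program instead of killing them. To find drugs with that activity in
expression compendia, one needs a scalar readout of *how far along a
lineage* a transcriptome sits.

`lmindex` treats a log2 expression profile as a point in gene space. A
**reference lineage vector** is fixed by two endpoint profiles: an immature
cell type $a$ (e.g. hematopoietic stem cells, replicate-averaged) and a
mature cell type $b$ (e.g. granulocytes). Only genes whose endpoint
expression differs by at least 4-fold — 2.0 log2 units, inclusive — enter
the vector; on those $N$ genes the **Lineage Maturation Index** of a sample
$c$ is the scalar projection of $c - a$ onto $b - a$:

$$
\mathrm{LMI}(c) \;=\; \frac{(b-a)\cdot(c-a)}{\lVert b-a \rVert}
\;=\; \frac{\sum_{i=1}^{N}(b_i-a_i)(c_i-a_i)}
           {\sqrt{\sum_{i=1}^{N}(b_i-a_i)^2}} .
$$

The score is 0 at the immature endpoint, $\lVert b-a\rVert$ at the mature
endpoint, and exactly linear along the segment between them; components of
$c$ orthogonal to the lineage direction do not move it. Larger LMI = more
differentiated. The units are log2-expression units; only *within-vector*
comparisons are meaningful, which is why the screen works on changes in LMI
rather than absolute values. A convenience rescaling,
`relative_maturity()` = LMI / norm, maps the endpoints to 0 and 1 but is
never used in screening decisions.

Assumptions worth keeping in mind:

* maturation is modeled as a straight segment in log2 gene space — staged
  intermediates are assumed to order along that segment even if they do not
  lie on it;
* the endpoint profiles are trusted: noise or batch effects in $a$ and $b$
  rotate the vector itself;
* all profiles are already normalized to a common log2 scale (normalization
  is upstream of this package).

## Gene filtering

`select_lineage_genes()` keeps genes with $|b_i - a_i| \ge$ `min_log2_diff`
(default 2.0 log2 units = 4-fold, inclusive at the boundary). The filter is
applied to the **absolute** difference: the projection uses signed
differences, so a gene silenced during maturation is as informative as one
induced. The selection is symmetric in the endpoints and shrinks
monotonically as the threshold rises. Vectors are serialized with the
threshold and norm recorded in the file header so a run's gene universe is
reproducible exactly.

The filter is fixed once, at vector-construction time, and reused for every
data set scored against that vector — recomputing it per data set would
silently change the score's geometry.

## Partial gene coverage

A scored sample must by default contain every lineage gene
(`min_coverage = 1`). When matrices from other platforms drop some lineage
genes, `min_coverage` may be lowered; missing genes are then removed from
the numerator **and** the norm is recomputed on the covered subspace, so
the result remains a genuine scalar projection (on a slightly different
vector) rather than an imputed value. Scores computed at different coverage
are not exactly comparable; the safe workflow is to harmonize gene spaces
first (`harmonize_gene_space()`) and keep coverage at 1.

## The drug screen

Drug-response compendia are organized in experimental batches, each with
its own vehicle (DMSO) controls. For every sample,

$$ \Delta\mathrm{LMI} = \mathrm{LMI} - \overline{\mathrm{LMI}}_{\text{controls in the same batch}}, $$

which removes batch-level shifts by construction (adding a constant to all
LMIs in a batch leaves its $\Delta$LMIs unchanged). `screen()` then
summarizes each treatment by its mean $\Delta$LMI, tests its per-sample
LMIs against control LMIs with a two-sided two-sample t-test, and ranks
treatments by descending mean $\Delta$LMI, breaking ties lexicographically
for determinism. Singleton treatments (common in repurposing compendia)
keep their shift and rank but get no p-value.

Choices made where the design was genuinely open:

* **Which controls to test against.** The $\Delta$LMI definition is
  batch-matched, so the default test group is the pooled controls of the
  batches containing the treatment's samples; `controls = "pooled-all"`
  uses every control instead (more power, more batch confounding).
* **Test variant.** Welch (unequal variances) is the default since
  treatment and control group sizes and variances routinely differ; the
  classical pooled Student test is available as `variant = "pooled"`.
* **Multiplicity.** The default flags treatments at raw p < `alpha`
  (0.05), matching the screen's role as a hypothesis generator whose hits
  go to the bench; Benjamini–Hochberg adjustment is available with
  `adjust = "bh"`, and when active the flag is applied to the adjusted
  values (always a subset of the raw flags).
* **Degenerate tests.** Two identical constant groups carry no evidence and
  return $t = 0,\ p = 1$; two constant groups with different means admit no
  finite t statistic and raise a degenerate-test error, which `screen()`
  downgrades to a warning and an `NA` p-value for that treatment.

## Synthetic data: what it does and does not emulate

`simulate_lineage()` builds a staged lineage: baseline log2 intensities
uniform in [4, 10] (the usual normalized-microarray range), endpoints
separated on exactly `n_signature_genes` genes by log2 magnitudes uniform
in [2, 4] with random signs — so the 4-fold filter recovers the planted
signature exactly in the noiseless limit — and by a sub-threshold drift
uniform in (−1, 1) elsewhere, modeling ordinary between-cell-type wobble.
Stage $s$ of $S$ sits at true maturity $t_s = s/(S-1)$ on the segment, plus
i.i.d. Gaussian noise (`noise_sd`, log2 units) on every value. Defaults
(1000 genes, 200 signature genes, 8 stages, `noise_sd` 0.2) mirror the
staged-lineage validation conditions.

`simulate_screen()` plants a screen on an existing vector's gene set: every
array sits at baseline maturity $t_0 = 0.2$ — a differentiation block near
the immature end — and arrays of the `n_positives` planted drugs are
shifted toward maturity by `effect_size` lineage norms (default 0.3, i.e.
30% of the immature→mature distance, with 3 replicates per drug and
`noise_sd` 0.1). Arrays are dealt round-robin into batches; each batch gets
its own DMSO controls at baseline. The batch count (10) and controls per
batch (2) are fixed package choices echoing the small per-batch control
counts of public drug-response compendia.

The generators are deterministic given their `seed` and emulate exactly
what the method consumes: a linear maturation axis, homoscedastic Gaussian
log2 noise, and clean batch structure. They do **not** emulate probe-level
artifacts, heteroscedastic or correlated gene noise, batch effects that
tilt the lineage direction itself, dose–response structure, or off-axis
drug signatures. Tests passing on these data therefore certify the
geometry, the bookkeeping and the statistics — not robustness to every
failure mode of real arrays.

## Numerical choices

* Projections accumulate in double precision via R's `sum()`/`crossprod()`
  (long-double accumulators); agreement with a naive explicit loop is
  verified to 1e-9 relative error on profiles up to $10^4$ genes, the
  regime this package targets.
* The filter boundary is inclusive and evaluated with ordinary
  floating-point comparison; thresholds are user-visible constants, never
  fuzzed.
* Ties in screen ranking are broken by treatment name via a stable sort, so
  output order is reproducible across platforms.
* Validation problem sizes (package choices, also used by
  `scripts/acceptance.R`): 1000 random projection triples of 10–$10^4$
  genes; 20 lineage seeds; 100 screen seeds for both the planted-recovery
  and null-calibration checks (5000 null tests total).

## Known limitations

* A single straight lineage: branching trajectories, curved manifolds and
  pseudotime models are out of scope; scoring a branch-committed cell
  against the wrong lineage vector yields a number without biological
  meaning.
* The score inherits any distortion of the endpoint profiles; endpoint
  replicates should be averaged (`average_replicates()`) and come from the
  same normalization as the scored samples.
* Gene-space harmonization works at the identifier level (intersection
  plus an optional many-to-one mapping collapsed by arithmetic mean);
  probe-level reprocessing across platforms is upstream prior work.
* Null calibration of the Welch test at n = 3 replicates is approximate;
  with very few replicates the ranking by mean $\Delta$LMI is the primary
  readout and p-values are supporting evidence.
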