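---
title: "Methods: modelling gene expression cascades along pseudotime"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling gene expression cascades along pseudotime}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pseudocascade)
```

## The problem

Pseudotime methods order single cells along a continuous process such as
differentiation. Most downstream tools then examine genes one at a time.
This package treats the *joint* picture: which genes switch on or off, in
what order, and which biological programs those switching stages carry.
The input is a preprocessed (filtered, normalized) genes × cells
expression matrix and a cell ordering from any trajectory method;
pseudotime inference itself is out of scope, as is normalization.

## Per-gene temporal model

For gene $j$ with expression $y_{ij}$ at ordered cell $i$ (pseudotime
$t_i$, by default the rank $i$), we fit a Gaussian cubic regression
spline,

$$ y_{ij} = f_j(t_i) + \varepsilon_{ij}, \qquad
   f_j \in \text{span}\{\text{natural cubic basis, } df = 3\}, $$

and test $H_0: f_j \equiv \text{const}$ with a likelihood-ratio statistic
$2(\ell_1 - \ell_0) = N \log(\mathrm{RSS}_0 / \mathrm{RSS}_1)$ referred to
$\chi^2_{df}$. P-values are Benjamini–Hochberg adjusted across all genes
and genes with $q < \alpha$ (default $0.05$, strict) are retained. The
Gaussian response is appropriate because the matrix is expected to be
normalized already; a count model is deliberately not offered.

Choices a user can change:

* `df` (default 3): spline basis dimension. Three basis functions resolve
  monotone and single-bump shapes while keeping the null test honest at
  small $N$; the fit requires $N \ge 2(df+1)$.
* `alpha` (default 0.05): BH retention level.

A gene with zero variance gets $p = 1$; a gene whose fit fails
numerically is kept with $p = 1$ and a warning rather than aborting a
whole run.

## Switch points and patterns

Retained genes' fitted values are scaled to mean 0, sd 1 (sample sd,
$n-1$ denominator). The switch points of gene $j$ are

$$ S_j = \{\, i \in \{1, \dots, N-1\} : x_{ij}\, x_{i+1,j} < 0 \,\}, $$

the cells where the scaled fitted trajectory crosses zero — the
transitions between low and high expression. Because the strict product
rule is blind to exact zeros, runs of exact zeros are collapsed: when the
nonzero neighbours flanking a zero run have opposite signs, one switch is
recorded at the last index before the run. Exact zeros essentially never
arise from real fits; the rule only pins down floating-point edge cases.

The sign sequence of the trajectory's constant-sign segments (each
segment's sign taken from its entry of largest absolute value, which is
robust to near-zero boundary values) classifies the gene: `-+` increasing,
`+-` decreasing, `-+-` up_down, `+-+` down_up, anything else `complex(k)`
with $k$ switch points.

## The cascade ordering

Genes are grouped by pattern; groups are ordered by increasing complexity
(number of switch points), so monotonic genes precede non-monotonic ones.
Within equal complexity the groups follow the sign strings
lexicographically with `-` before `+` — increasing before decreasing,
up_down before down_up. That tie-break is this package's convention; only
"monotonic before non-monotonic" is intrinsic to the method. Within a
group, genes sort by first switch index, remaining ties by gene id, so
re-running always reproduces the identical permutation. Ranks $1..G$ are
the heatmap row order; figures never re-sort, and every figure writes a
sidecar TSV of exactly what was rendered.

Alternative orderings (complete-linkage hierarchical leaves, k-means with
clusters concatenated by centroid first-crossing) are provided purely for
visual contrast; they are not part of the cascade definition.

## Multiple samples

With a cell→sample assignment, the entire fit–scale–detect–classify chain
runs independently per sample. A gene is *consistent* when it is retained
in every sample with an identical sign string. Switch positions are
compared on the fraction scale $i/N_s$ because samples differ in cell
count; for each switch ordinal the cross-sample summary is
$\bar{p} \pm 2\,\mathrm{sd}(p)/\sqrt{m}$, clipped to $[0,1]$
(`summarizeSwitchFractions()`). The consensus heatmap order uses the mean
first-switch fraction within pattern groups — the single-sample rule with
the mean fraction in place of the index.

A caveat worth stating plainly: the ±2 SE interval summarizes
*between-sample* variability only. Any estimator bias shared by all
samples — e.g. the df = 3 smoother systematically shifting a sharp
sigmoid's crossing toward the trajectory centre by up to ~0.03 of the
axis — moves every sample identically and is invisible to this interval.
The interval describes the reproducibility of the estimated position, not
its distance from a hypothetical true switch time.

## Enrichment

Over-representation uses the upper-tail hypergeometric test. Two
definitions deserve emphasis:

* **GeneRatio** is `count / (background genes annotated with the term)` —
  the term's coverage by the query — *not* the more common
  count-over-query-size. Rankings and dot plots use this definition.
* **Background** is the set of significance-retained genes that appear in
  the annotation universe. Testing within the trajectory's own gene set
  avoids trivially rediscovering "is temporally variable" for every term.

Per-pattern analysis tests each term against one pattern group's genes,
BH-adjusts within the group's tests (the "q-value" is BH throughout, for
consistency with the retention step), ranks by GeneRatio (ties: p-value,
then term id) and keeps the top 10 by default.

Temporal analysis slides a window along one pattern group's cascade
order: window size $\lceil G / n_\text{windows} \rceil$, non-overlapping
by default (overlap configurable), so each gene belongs to exactly one
window. Each window is tested and BH-adjusted separately; the display set
is the union of each window's top 5 terms by GeneRatio, filtered to
$q < 0.05$. Window count (default 10) is fully user-settable — the right
granularity depends on how many genes the group holds.

## The synthetic-data generator

`simulateDataset()` plants known structure so every stage can be scored
without external data:

* increasing genes: amplitude × logistic sigmoid over the pseudotime
  fraction; decreasing genes are the mirror image;
* up_down / down_up genes: a Gaussian bump (sd 0.12 of the axis) or its
  negation, giving two crossings;
* null genes: constant plus noise;
* Gaussian noise (sd 0.3 by default) on the normalized scale, matching
  the Gaussian fitting family;
* across samples, each gene's crossing fraction is jittered by a
  truncated normal (sd 0.03 by default).

Defaults (300 cells; 150/150/100/100 patterned plus 100 null genes;
amplitude 1) are the study-scale conditions the validation suite runs at.
The planted fraction $t^\*$ is defined as the point where the *noiseless
scaled trajectory crosses zero* — the quantity the method estimates — and
the sigmoid centre is calibrated by root-finding to put the crossing
exactly there; planting the raw sigmoid midpoint instead would offset the
crossing by roughly width × logit(1−t\*) after mean-centring. The sigmoid
width default is 0.08 of the axis: narrow enough that a genuine interior
switch can sit at fraction 0.25 or 0.75 (wider sigmoids can only reach
those fractions with degenerate saturated curves), wide enough that the
df = 3 smoother tracks the transition.

What the generator does **not** emulate: count noise, dropout,
library-size variation, gene–gene correlation, or uncertainty in the
ordering itself. Passing tests therefore demonstrate the pipeline's
statistical behaviour on smooth normalized signals with independent
Gaussian noise — not robustness to raw scRNA-seq artefacts, which the
required preprocessing is assumed to have handled.

## Numerical choices and degenerate inputs

* Likelihood ratio uses the exact Gaussian profile form
  $N \log(\mathrm{RSS}_0/\mathrm{RSS}_1)$, truncated at 0; a perfect fit
  ($\mathrm{RSS}_1 = 0$) maps to $p = 0$.
* Scaling tolerances: scaled trajectories satisfy |mean| < 1e-8 and
  |sd − 1| < 1e-8; BH agrees with a step-up oracle to 1e-12;
  hypergeometric tails agree with factorial sums to 1e-12.
* Orderings must be strictly increasing in pseudotime; ties are an error
  rather than silently broken.
* Cells present in the matrix but missing from the ordering are dropped
  with a message (orderings often cover one branch); a cell in the
  ordering but not the matrix is an error.
* Empty cascades, header-only result tables, zero-width CIs and empty
  enrichment inputs are all legal degenerate outputs with warnings, not
  crashes.
* All switch indices are reported 1-based; cross-sample arithmetic is
  always on the fraction scale.

## Problem sizes in the validation suite

The test suite and `scripts/acceptance.R` run at the generator's default
scale: 600 genes × 300 cells for pattern recovery, 2 000 null genes for
the type-I check, 100 genes per planted fraction for localization, 200
genes × 5 samples for the CI construction, and an exhaustive
hypergeometric enumeration up to population 60. These sizes keep the
whole suite within a couple of minutes on one CPU while leaving the
statistical assertions well-powered.

## Known limitations

* Single linear orderings only — no branching trajectories, and no
  alignment of pseudotime scales across samples beyond the fraction
  normalization.
* The significance test is a plain LRT against a constant; it does not
  model pseudotime-estimation uncertainty and exact p-value parity with
  other smoother implementations is not expected.
* Flat gene sets only: no GO-DAG propagation or hierarchy-aware testing,
  and no depletion (under-representation) testing.
* Switch localization inherits the smoother's bias at df = 3 for very
  sharp transitions (see the multi-sample caveat above); increasing `df`
  sharpens localization at some cost in null-test calibration.
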