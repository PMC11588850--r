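---
title: "Methods: analysing regulatory-network adaptation after regulator knockouts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: analysing regulatory-network adaptation after regulator knockouts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trnadapt)
```

# The analysis problem

When a transcription factor (TF) is deleted from a bacterium and the strain
is serially evolved back to fitness (knockout adaptive laboratory evolution,
KO-ALE), the route the cell takes depends on the regulator's context: how
active it was on the growth condition, how large and how redundant its
regulon is, and how central it sits in the transcriptional regulatory
network (TRN). `trnadapt` implements the quantitative layer of such a study:

* rescaling ICA-derived regulatory-module (**iModulon**) activities onto a
  **basal activity** scale on which zero means "no regulatory activity";
* scoring and selecting regulators for knockout from regulon size, measured
  KO growth defect, and explained expression variance;
* directed TF-graph statistics that anticipate adaptation outcomes
  (reachability, betweenness, node-removal impact, regulon subnetwork
  skewness, sole-regulator counts);
* converting kinetic phenotyping-plate opacity curves into binary
  growth/no-growth calls with family-wise error control;
* detecting convergent mutations across independent evolution lineages; and
* combining these into a four-category classification of each KO strain.

A synthetic-data module generates all six input artifacts with known ground
truth, so every stage is testable end to end.

# The ICA data model and the basal transformation

Independent component analysis factors a log-scale expression compendium
$X$ (genes × samples) as $X \approx M A$, where columns of $M$ are gene
weightings (iModulons) and rows of $A$ their activities per sample. The raw
sign of an activity row is arbitrary: a high value can mean either more or
less regulation. The basal transformation fixes this.

Each iModulon is assigned a **direction**. When knockout samples of the
linked regulator are available they anchor the no-activity end empirically:
in a KO the module literally cannot act, so if the mean KO raw activity lies
above the median of the reference compendium, the high end is the
no-activity end (direction $+1$), otherwise the low end ($-1$). Exact ties
resolve to $-1$ with a warning. Without KO samples an annotated direction
from the regulator's known function is required — there is no formula that
can substitute for that biological knowledge, so we make the annotation an
explicit input rather than guessing.

The activity row is then shifted so that "no activity" sits at about zero:
for direction $-1$, subtract the 5th quantile of the row over the
*reference* samples ($A' = A - q_{0.05}$); for direction $+1$, use the 95th
quantile and flip ($A' = q_{0.95} - A$), negating the matching $M$ column so
the reconstruction $M'A'$ stays sign-consistent with $M(A - q)$. Quantiles
use linear interpolation between order statistics (R type 7), fixed for
reproducibility. Quantiles rather than extremes keep single outliers from
setting the baseline; the cost is that up to 5% of reference samples (plus
one order statistic) sit slightly below zero. We deliberately do **not**
clamp those small negatives — they carry information about the tail and
clamping would destroy the exact invertibility of the transform, which the
test suite verifies to $10^{-12}$.

Two scoping choices deserve note. The quantile offsets are computed over
reference-compendium samples only, never over study samples: KO samples sit
at the no-activity extreme by construction and would drag the baseline
toward themselves. And a warning is raised below 20 reference samples,
where a 5% quantile is essentially an extreme order statistic.

# Selecting regulators and classifying their adaptation

Candidate regulators are scored three ways: regulon size (distinct
annotated targets), the measured growth defect of the unevolved KO
(candidates need at least a 20% defect by default), and the variance of the
regulon's expression explained by the linked iModulon,
$R^2 = 1 - \lVert X_G - M_{G,k}A_k\rVert_F^2 / \lVert X_G\rVert_F^2$ with
per-gene centering applied to both terms. The growth-impact score of a
regulator is the summed deletion growth defect of its repressed targets
minus that of its activated targets; dual-effect targets are excluded by
default (counting them in both sums cancels exactly, and is available as an
option), and z-scores standardize the score distribution with the $n-1$
deviation.

Each evolved KO strain lands in one of four categories, tested in a fixed
order:

* **iv** — growth did not recover (mean endpoint lineage rate below 95% of
  the wildtype rate; the 95% operationalizes "growth data overlaps the
  wildtype" and is configurable);
* **i** — growth recovered and the regulator was inactive on the condition:
  wildtype basal activity of its iModulon below the activity threshold;
* **iii** — growth recovered, regulator active, and a convergent mutation
  hit the regulator's network: its regulon, a regulator of an overlapping
  iModulon, or a configured post-transcriptional partner (this last clause
  captures small-RNA partners that annotated regulons miss);
* **ii** — growth recovered, regulator active, no regulator-specific
  mutations.

The activity threshold defaults to 10% of the iModulon's reference basal
maximum. No numeric cutoff is inherited from prior work here; 10% of the
observed dynamic range is small enough that a genuinely active module
clears it by a wide margin and large enough that quantile noise around zero
does not, and the synthetic archetypes confirm the margin (wildtype basal
around 8 activity units against thresholds near 2).

# TF-graph statistics

The TF graph keeps only genes that act as regulators, with a directed edge
$u \to v$ when $u$ regulates $v$; self-loops are dropped and parallel
records collapse (effect signs matter for the impact score, not for graph
topology). On this graph the package computes the weak-component fraction,
**pair connectivity** (the fraction of ordered TF pairs joined by a
directed path), the impact of deleting one node on that fraction (reported
both as the new value, "drops to", and the relative drop, "drops by" —
published phrasings mix the two, so both are returned), normalized directed
betweenness, and the fraction of shortest paths through a node.

Ordered pairs over *all* regulator nodes (including isolated ones) form the
connectivity denominator. The published statistic does not say whether
pairs are ordered or whether isolated regulators count; ordered pairs over
all nodes match the directed-network framing and keep node-removal
comparisons well defined, so that is the fixed convention here.

`path_through_fraction()` has two modes. `"pair"` (default) asks: among
ordered pairs with a path that avoid the focal node as endpoint, for what
fraction does the node lie on at least one shortest path? `"path"` averages
the per-pair fraction of shortest paths through the node (path counts with
multiplicity), which makes the value times the number of eligible pairs
exactly the node's Brandes betweenness numerator — the form consistent with
the betweenness statistic reported alongside it. Both the pair-mode and
path-mode values, pair connectivity, removal impacts and betweenness are
checked against an exhaustive shortest-path enumeration oracle on 200
random digraphs to $10^{-12}$.

Regulon subnetwork skewness takes the subnetwork induced by a TF and its
targets (all regulatory records among those genes), computes total degree
(in + out), and returns the population Fisher–Pearson skewness $g_1$; the
bias-adjusted $G_1$ is an option. Zero degree variance is reported as `NA`
with a warning rather than a number.

# Growth calling from kinetic plates

Opacity traces (48 h, 192 reads in the synthetic default) are smoothed with
a Savitzky–Golay filter. The classical filter needs an odd window, so the
conventional window of 50 becomes 51 with a notice; degree 3 is the
default. Boundary points are fitted on the one-sided window, so cubic
traces are reproduced exactly everywhere. Whole plates are smoothed with a
single precomputed projection-matrix product, which is numerically
identical to filtering each trace.

The maximum smoothed signal per well is compared against the negative
controls: control mean $\mu$ and $(n-1)$ standard deviation $\sigma$, the
statistic $z = (s - \mu)/\sigma$, an upper-tail p-value, Bonferroni
correction across the tested wells of one plate (families are never pooled
across plates), and a growth call below $\alpha = 0.05$.

The p-value's reference distribution is the one genuinely open design
choice. Under Gaussian maxima with *estimated* control parameters the exact
null of $z$ is $\sqrt{1 + 1/n}\,t_{n-1}$, not standard normal. The
difference is not pedantry: simulation of null plates with 94 tested wells
shows the plain normal tail inflates the family-wise false-call rate to
roughly 0.54, 0.25 and 0.21 at 2, 8 and 12 control wells, and it remains
near 0.09 even at 64 controls — the Bonferroni guarantee is unattainable.
With the $t$ reference the rate is 0.03–0.045 at 12 controls, and power at
a 10-standard-deviation effect still exceeds 0.999. `growth_calls()`
therefore defaults to `reference = "t"`; `reference = "normal"` reproduces
the plain one-sided z-test exactly for comparison with analyses that used
it. Only the upper tail is offered: growth means more opacity.

PCA of the binary call matrix is computed by singular value decomposition
of the column-centered, unscaled matrix. Centering without scaling keeps a
condition's leverage proportional to its call variance, which is the
natural weighting for binary data; zero-variance conditions are dropped
with a warning.

# Convergent mutations

A mutation converges when its gene-or-region label is hit in at least two
*distinct* lineages of a KO ("at least two evolved strains" and "at least
two independent lineages" are treated as the same rule). Grouping is by
label, not exact position, because promoter-region mutations of the same
gene at neighbouring positions are one adaptive signal; positional keys
remain available through the Jaccard machinery. Population-sample records
count toward convergence down to a frequency floor of 0.05 — low-frequency
subpopulation mutations can carry real adaptations — and the floor is
configurable. Isolate–population agreement is the Jaccard index over
(position, allele) keys by default, with gene-level keys as an option; the
empty–empty case is an explicit error, not a 1.

# The synthetic-data generators

The generators define the study conditions under which the pipeline is
validated. Their defaults are fixed once and describe a scaled-down
regulator KO-ALE study; the scaling keeps the full validation suite within
tens of seconds on one CPU.

* **TRN**: 20 TFs and 180 target genes, TF→gene density 0.04, TF→TF
  density 0.08, one hub TF forced to at least five times the median
  out-degree, ten genes reserved with exactly one regulator, and at least
  two targets per TF (curated regulators have annotated targets by
  definition). Effects are sampled 55% activation / 40% repression / 5%
  dual.
* **Expression**: 100 reference samples stand in for a large compendium;
  12 iModulons, each loading only on one regulator's regulon with weights
  of magnitude 0.5–1.5 signed by effect. Underlying activities are
  exponential with mean 5 (right-skewed: mostly low, occasionally high,
  which matches how a condition-specific module behaves across a
  compendium and keeps the 5% reference quantile near zero). Raw rows
  encode activity with a random recorded direction; KO samples carry
  exactly zero activity of their own iModulon. Expression is $MA$ plus
  additive Gaussian noise (sd 0.25 log-units); the noise matrix is stored
  so tests can verify the residual exactly.
* **KO archetypes**: effect size 0 (inactive, category i), 8 with no
  planted convergence (ii), 8 with one convergent regulon gene (iii), and
  a non-recovering hub (iv). Recovery draws endpoint rates at 96–102% of
  wildtype; non-recovery at 70–88%.
* **Mutations**: background mutations are Poisson with mean 7.3 per
  endpoint isolate — the per-isolate mutation load reported for this kind
  of experiment is used directly as the study condition — drawn *without
  replacement across lineages* from the non-planted gene pool. Real ALE
  background mutations are overwhelmingly non-convergent; partitioning
  makes that exact, so planted genes are provably the only convergent ones
  and ground truth is unambiguous. Population samples copy their endpoint
  isolate's records (frequencies 0.5–1) plus extra subpopulation mutations
  with Poisson mean 4.78, which sets the expected isolate–population
  Jaccard index near 0.60, matching the agreement level reported for
  population versus clonal sequencing.
* **Plates**: 106 wells = 12 negative controls + 94 tested, baseline 30
  opacity units, well-to-well baseline sd 2, per-read noise sd 2, logistic
  amplitude 150 with random rate (0.25–0.5 h⁻¹) and midpoint (12–28 h).
  Twelve controls is the smallest round count at which the t-referenced
  z-statistic is both valid and near-fully powered (see above).
* **Binary call matrices** for PCA validation: strains have bimodal
  nitrogen-utilization ability (growth probability 0.1 or 0.9 on
  nitrogen-limited conditions) while other conditions flip with
  probability 0.03. Bimodality mirrors the observed pattern that evolved
  strains either lose most nitrogen substrates or almost none.

All generators derive their streams from the single spec seed with small
fixed offsets, so artifacts are bit-reproducible and independently
regenerable.

What the generators do *not* emulate: ICA estimation noise and component
splitting/merging, plate-reader drift or edge effects, hypermutators
(excludable in `mutation_summary()` but not generated by default),
linkage between mutations, and any real gene identity. Passing tests
therefore demonstrate that the pipeline's logic and guarantees hold under
its stated statistical assumptions — not that those assumptions hold for
any particular real dataset. Statistics tied to external curated snapshots
(component fractions, connectivity drops, shortest-path fractions of a
real TRN) are exercised here only on synthetic networks; with a real
regulon export they are one `read_regulon()` call away.

# Differential activity and operon-level expression

No specific published model is reproduced for differential iModulon
activity; the package provides a deliberately simple, fully documented
substitute: the absolute mean basal-activity difference, a label-permutation
p-value (10,000 permutations by default, seeded), Benjamini–Hochberg
adjustment across iModulons, and a flag only when the difference also
exceeds 5 basal-activity units. The effect-size gate keeps trivially small
but significant shifts out of the reported set.

Differentially expressed operons (DEOs) summarize gene-level log2 fold
changes as the operon mean; significance uses a two-sample t-test on
per-replicate operon means. Pooling raw gene-replicate values instead would
mix gene-to-gene baseline differences into the within-condition variance,
so the per-replicate operon mean is used. Thresholds default to |log2FC| >
1 and BH q < 0.05; operons without measured genes are skipped with a
warning.

# Numerical and degenerate-input conventions

Quantiles are type 7 throughout. Zero-variance controls, empty regulon
tables, empty gene sets, overlapping comparison groups, missing directions
and sub-minimum graphs raise errors; undefined-but-survivable quantities
(relative drop from zero connectivity, zero-variance skewness) return `NA`
with a warning. Greedy iModulon matching breaks correlation ties by column
order, and `select_candidates()` breaks defect ties by regulator id, so
outputs are order-independent. The pipeline report is a pure function of
(config, seed) and reruns are byte-identical.

# Known limitations

The classification consumes one iModulon per regulator (the first
annotated); regulators with several modules of opposing condition activity
need per-module inspection. The convergence rule counts lineages, not
evolutionary events — back-to-back sweeps in one lineage count once.
Explained variance uses a rank-one reconstruction per iModulon and ignores
cross-module covariance. The growth caller assumes approximately Gaussian
well maxima under the null; plates whose no-growth wells have strongly
skewed maxima would need a calibration run. None of the numeric results in
this vignette are asserted from memory: every quantity cited here is
recomputed by the test suite or by `scripts/acceptance.R`.
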