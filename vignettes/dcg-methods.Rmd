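---
title: "Multiscale data cloud geometry for connectivity matrices: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale data cloud geometry for connectivity matrices: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcgnet)
```

## The problem

Functional brain connectivity is commonly summarized as an ROI-by-ROI
correlation matrix — here 106 regions of interest spanning 10 anatomical
regions, one matrix per subject and task condition ("green" and "red"
trials).  Such a matrix carries structure at several scales at once: tight
left/right homologue pairs, anatomical region blocks, and the global
network.  Each subject's matrix also sits on its own unknown measurement
scale, so comparing raw matrices across subjects is meaningless; what can
be compared are *clustering structures* extracted at matched scales.
`dcgnet` implements a multiscale clustering geometry for such matrices and
the supervised classification built on top of it, together with a
synthetic cohort generator that makes the whole chain testable without any
private data.

## The clustering geometry

### Temperature and the power transformation

For a correlation $r_{ij}$ the similarity at temperature $T$ is

$$ s_{ij}(T) = |r_{ij}|^{1/T}. $$

$T$ acts like the focus knob of a microscope.  As $T \to 0$ every
similarity collapses to 0 except those with $|r|$ very close to 1, so only
the tightest bonds (the pair motifs) remain visible.  As $T$ grows all
similarities approach 1 and the cloud merges into a single cluster.  The
unknown per-subject scale multiplies $1/T$ inside the exponent, so sweeping
a wide $T$ range makes it irrelevant.  The default grid
(`default_t_grid()`) has 40 logarithmically spaced points in
$[10^{-3}, 5]$; the lower end is the fine scale used for motif extraction
and the upper end is comfortably inside the one-cluster regime for
matrices whose off-diagonal correlations are at least about 0.1 in
magnitude.

### Regulated random walks and cluster sharing

At a chosen temperature, cluster information is extracted by an ensemble of
*regulated random walks* (`sharing_matrix()`, with the single-walk
mechanics in `run_regulated_walk()`):

* from the current node the walk moves to a not-yet-removed node $j$ with
  probability proportional to $s_{\text{cur},j}$;
* a node is removed at its $m$-th visit (default $m = 3$) — the
  recurrence-time regulation;
* after a removal the walk continues from the removed node's similarity
  row, so a tight cluster is exhausted before the walk drifts onward;
* if the current row has no mass on the remaining nodes, the walk
  teleports to a uniformly random active node.

Because every step is exactly one visit, a walk terminates after at most
$mn$ steps.  The removal order is then segmented: a boundary falls at
every teleport, at every removal-step gap above
$\text{mean} + c \cdot \text{sd}$ of the walk's gaps (default $c = 1$),
and between consecutive removals whose mutual similarity is below
$10^{-4}$ times the smaller of their row maxima.  The last rule is
deliberately *row-relative*: at very small $T$ the absolute similarities of
two equally genuine pair bonds can differ by dozens of orders of
magnitude, while the walk follows either with relative probability near 1.
A row-relative test is the only scale-free way to distinguish "the walk
happened to saturate two unrelated stragglers back-to-back" from "these
nodes are cluster mates", and without it late-walk stragglers from
different clusters weld into spurious segments.

The cluster-sharing probability matrix $P$ records, for each pair of
nodes, the fraction of walks in which the pair fell into one removal
segment.  With the default `n_walks = 100` the entries have Monte-Carlo
standard errors below 0.05, which is ample for the spectral counting and
tree cuts downstream; all walks of one ensemble are driven by a single
seeded RNG stream, so results are bit-for-bit reproducible.

### Counting clusters and cutting the tree

The number of clusters at a temperature is the number of significantly
non-zero eigenvalues of the symmetrically normalized sharing matrix
$D^{-1/2} P D^{-1/2}$, operationalized as the eigengap rule: with
eigenvalues sorted decreasingly, $K$ is the position of the largest
consecutive gap, taking the gap after the smallest eigenvalue against
zero (`estimate_cluster_count()`).  On an exact block-diagonal $P$ each
block contributes one unit eigenvalue and the rule returns the block count
for any block sizes; the identity matrix gives $K = n$ and the all-ones
matrix $K = 1$.

Memberships come from cutting a hierarchical tree on the dissimilarity
$1 - P$ (`cluster_level()`).  Two linkages are used deliberately:

* **fine scale (motifs)**: complete linkage, pruned at a fixed height
  (default 0.85), so that only branches whose members *all* share high
  sharing probability survive as motifs;
* **count-based cuts (coarse levels)**: average linkage.  When the sharing
  graph decomposes into exactly $K$ connected components, the
  average-linkage cut at $K$ returns precisely those components, because
  the average dissimilarity between two components is exactly 1.  Complete
  linkage does not have this property: inside a weakly knit block the
  maximal dissimilarity can also reach 1, and the cut then splits blocks
  arbitrarily instead of following the graph.  This matters exactly at the
  temperatures where regions are internally sparse but still connected.

### Tuning to a common scale

`cluster_trajectory()` traces $K$ over the grid; the raw, unsmoothed
estimates are reported.  The typical trajectory starts at the motif
plateau (around 50–60 clusters), drops steeply, pauses near the regional
scale, and converges to 1.  `critical_temperatures()` reports the grid
midpoints whose drop in $K$ is at least half the largest drop.

`tune_to_count()` selects the clustering level whose count is closest to a
target (10 for the regional scale here).  Two robustness devices are
applied, both motivated by the fact that a common scale is only meaningful
if it is stable under small temperature changes: the selection runs on a
3-point running median of the trajectory (suppressing isolated spurious
counts in the transition zones), and among equally good attainments the
*highest* temperature wins — the low-temperature shoulder of a count
plateau can attain the same count while its blocks are still internally
fragmented, whereas the coarse end of the plateau has consolidated them.
The achieved count is reported and may differ from the target by one or
two; downstream code treats that as information, not as an error.

## Coarse-scale features

With every subject tuned to the 10-cluster level, concordance with the
10-region anatomical atlas is measured by the Rand index — the proportion
of ROI pairs on which the two partitions agree (`rand_index()`).  The
55 retention features (`retention_features()`) are the per-region
proportions of within-region ROI pairs that still share a cluster
(10 intra features) and the per-region-pair proportions of cross-region
pairs that share a cluster (45 inter features), ordered intra-first in the
canonical region order.  A shared cluster is read as a retained functional
link, so the inter features quantify surviving long-range connectivity;
screening uses Welch two-sample t-tests with sign ASD minus TD and a raw
p-value cutoff (default 0.105), with no multiplicity correction because
the screen selects features rather than testing hypotheses
(`screen_features()`).

## Fine-scale features

At $T = 0.001$ the geometry decomposes into small core clusters — motifs,
mostly left/right pairs.  A subject-trial's motif configuration is the set
of pruned-tree branches with at least two members; singletons are
excluded, and a motif's identity is the exact sorted tuple of its ROI ids.
Pooling one group-trial's configurations gives a motif domain with a
prevalence function (`motif_domain()`); restricting at a prevalence
threshold $\tau$ keeps motifs carried by at least $\tau$ subjects.

Two aspects of a configuration relative to the restricted domains carry
the discriminative information:

* the **odds score**: the sum over motifs present in both restricted
  domains of $\log$ of the relative prevalence ratio,
  $\log\frac{\text{prev}_A(m)/n_A}{\text{prev}_T(m)/n_T}$.  The exact
  functional form of this score is a design choice of this package: a sum
  of log ratios is the numerically stable, monotone equivalent of a
  product of prevalence odds.  Prevalence is normalized *within each
  domain* because a subject's own-group domain is a jackknifed 28-subject
  ensemble while the opposite domain has all 29 members; with raw counts
  the systematic $\log(28/29)$-scale offset per motif accumulates over the
  ~40 common motifs into an artificial group separator strong enough to
  classify a null cohort almost perfectly.  With equal-size domains the
  score reduces to the plain log prevalence ratio (a motif carried by 10
  ASD and 21 TD subjects scores $\log(10/21)$: such a carrier is about
  twice as likely to be TD);
* the **missing-motif counts**: how many of the configuration's motifs are
  absent from the restricted ASD domain and from the restricted TD domain
  (`missing_counts()`).

For each subject these are computed per trial with the subject excluded
from its own group's domain (the jackknife) and the opposite group's
domain complete, giving the six components
$(\text{odds}, \text{miss}_A, \text{miss}_T)$ for green and red trials.
The classifier predictors are, per trial, the odds score and the
difference $\text{miss}_T - \text{miss}_A$ — four predictors in the
two-trial mode.  This transformation of the six components into four
predictors is likewise a documented design choice: it uses all six
components and is directionally interpretable (both predictors increase
with evidence for ASD membership).

## Classification

`loocv_classify()` runs leave-one-out cross-validation: for each held-out
subject a logistic regression with intercept is fit on the remaining
subjects' predictors and the held-out subject is classified ASD when its
predicted probability exceeds 0.5.  Sensitivity is the correct-ASD
fraction, specificity the correct-TD fraction, both reported with their
integer numerators.  In the default `"jackknife"` mode every subject's
features are computed once, with self-exclusion from its own group's
domain; `"per_fold"` mode additionally rebuilds all domains without the
held-out subject in every fold.  Strong synthetic signal separates the
training folds perfectly, in which case the fit falls back to a small
ridge penalty ($10^{-4}$ on standardized predictors) that keeps the
separating direction with finite coefficients.  Degenerate folds are
recorded as misclassifications with a warning, never dropped.
`tau_sweep()` tabulates sensitivity and specificity over
$\tau \in \{2, \dots, 22\}$ and the three trial modes.  Coarse retention
features can be added as extra predictors via `coarse_predictors()` and
the bundled variable sets (`coarse_variable_sets()`).

## The synthetic cohort generator

`simulate_cohort()` generates 29+29 subjects times two trials of
block-structured correlation matrices with planted ground truth.  The
template has three correlation levels: baseline 0.1 between unrelated
ROIs, 0.45 within each anatomical region, and 0.9 inside each planted pair
motif; consecutive odd/even ROI pairs are the motif candidates, mirroring
the left/right homologue pairing of the atlas.  Per subject and trial,
each motif is included independently with its group's inclusion
probability; symmetric Gaussian noise (sd 0.05; red trials 1.5× noisier,
reflecting their less stable correlation estimates) is added, and the
matrix is repaired to the nearest valid correlation matrix by eigenvalue
clipping and renormalization.

Default group structure: most pairs are common to both groups (inclusion
24/29, matching the high-prevalence motifs the method reports on real
cohorts); eight motifs are ASD-enriched and eight TD-enriched at 24/29 vs
4/29 (an expected prevalence gap of 20, the strong-signal regime in which
the learning rules should classify perfectly); and the pair (87, 88)
gets 10/29 vs 21/29 as a moderate TD-leaning motif.  Motif inclusion is
drawn independently per trial, modelling trial-specific functional
configurations.  The default regional shifts are mild within-region
*increases* (Parietal +0.08, Cingulum +0.06 in ASD): they alter regional
connectivity strength without dissolving the region blocks, so both
groups keep the same recoverable 10-region geometry.  A geometry-altering
shift — for example a +0.3 between-region increase, which visibly merges
two regions in the tuned 10-cluster level and is picked up by the feature
screen — can be planted explicitly when regional abnormality detection is
itself under study.  `null_cohort_design()` removes every group
difference for calibration runs.

What the generator does *not* emulate: fMRI time series and their
autocorrelation, the beta-series estimation step (its uncertainty is
abstracted into the single noise-sd knob), spatially structured noise,
motion artifacts, and heterogeneous per-subject measurement scales beyond
what the power transform absorbs.  Passing the planted-recovery and
classification checks therefore demonstrates the pipeline's internal
correctness and its behavior under the stated block-plus-noise model, not
performance on real cohorts.

A note on seeding: per-subject and per-walk seeds are derived from the
master seed with an avalanche-mixing integer hash.  Naive arithmetic
seed progressions (`seed + k * step`) produce measurably correlated
Mersenne–Twister streams — in one observed case the "null" cohort's two
groups differed by five standard deviations in a motif's inclusion count —
so the hash is load-bearing for the calibration guarantees.

## Numerical choices and degenerate inputs

* Symmetry, unit-diagonal and range validation use a $10^{-8}$ tolerance;
  errors name the offending ROI pair.
* Matrices are dense throughout ($n \approx 106$).
* At $T = 0.001$ similarities below roughly $10^{-323}$ underflow to zero;
  the walk's teleport rule makes this harmless (an isolated node is
  reached by teleport and becomes its own segment).
* An all-zero off-diagonal sharing matrix yields an empty motif
  configuration (all singletons), and a region with fewer than two ROIs
  would flag its intra feature as `NaN` (never the case for the bundled
  atlas).
* Ties in the eigengap go to the smallest count; ties in tuning go to the
  highest attaining temperature (see above).
* The bundled atlas file (`inst/extdata/atlas_106_synthetic.tsv`) carries
  synthetic coordinates: region centers on a fixed layout with
  deterministic offsets, pairs mirrored across the midline.  They exist
  for the edge-list export and 3-D plotting only and encode no real
  anatomy.

## Problem sizes used in the checks

The test suite and the acceptance script run the full default conditions:
29+29 subjects, 106 ROIs, 100 walks per sharing matrix, the 40-point
temperature grid for tuning, and three replicate null cohorts for the
chance-level calibration (averaging replicate cohorts tightens the
binomial noise of a single 29-subject group without touching the
tolerance).  Unit tests exercise the same code paths on reduced designs
(14 ROIs, 3 regions, 6–8 subjects per group).

## Known limitations

* The walk mechanics (visit-count removal, continue-from-removed-node,
  teleports) and the segment-boundary rules are this package's concrete
  realization of a regulated random walk with recurrence-time dynamics;
  other realizations could yield slightly different sharing matrices.
* The odds functional form and the four-predictor transformation are
  documented stand-ins (see above); both are centralized so alternative
  transforms can be swapped in.
* The eigengap count is ambiguous when block cohesion is strongly
  heterogeneous; the tuning layer compensates via median smoothing and
  plateau selection, but single-temperature counts in transition zones
  should not be over-interpreted.
* Sensitivity/specificity on 29-subject groups have binomial noise of
  about $\pm 0.09$; single-cohort chance-level estimates are accordingly
  coarse.
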