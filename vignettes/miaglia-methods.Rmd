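---
title: "Methods and design choices in miaglia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices in miaglia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miaglia)
```

miaglia packages the quantitative core of a maternal-immune-activation
(MIA) microglia study: expression-module discovery on developmental
microglial RNA-seq, cross-species gene-set enrichment, 3D spine and
microglia-contact morphometry, thymidine-analog fate-mapping demographics,
and cross-modality rank correlations. This vignette records the models,
the tunable parameters, and the choices made where the underlying
procedures are conventionally under-specified.

## The study design and the synthetic generator

The canonical design is 10 groups × 3 replicates = 30 samples: Saline and
MIA offspring at E17, P7, P20 and P60 on control chow, plus the two P60
microglial-repopulation (MG-REP) groups. `mia_design()` enumerates it;
`sim_counts()` draws a gene × sample matrix of negative-binomial counts
over that design.

The generator is a first-class, tested component, not a fixture. It
emulates:

* **Count noise.** Counts are NB with mean–dispersion parameterization,
  `variance = mu + phi * mu^2`, the family bulk RNA-seq count models
  assume. Default `phi = 0.1`, a typical biological-replicate dispersion.
* **Library sizes.** Log-normal around 1e7 with CV 0.2 — realistic
  sequencing depth variation without any external data.
* **Module structure.** Five planted modules (IM, MIA-IM, JM, AM, REP-AM),
  each upregulated by 4 log2 units in its characteristic age/condition
  groups. Default sizes are the observed module sizes scaled by one tenth
  (468/282/232/328/113), plus 300 unstructured background genes and the 25
  marker genes: desk-scale run times while preserving the feature that
  structured genes dominate the filtered transcriptome, as they do in real
  developmental microglia data.
* **Contamination.** Marker-gene expression is apportioned so each
  non-microglial cell type contributes its requested fraction of the total
  marker-panel signal in expectation; the default 0.5% per type (2% total)
  emulates a clean sorted-microglia preparation scoring ~98% pure.

What the generator does **not** emulate: length-dependent TPM effects (no
transcript lengths exist, so CPM serves as the TPM surrogate — the purity
statistic is a within-panel ratio and is invariant to any common per-sample
scale), batch structure, sex or litter effects, correlated gene–gene noise
beyond module co-regulation, and partially-overlapping module membership.
Passing tests therefore demonstrate algorithmic correctness and
calibration, not robustness to every artefact of real libraries.

Every generator takes an explicit integer seed and is byte-reproducible;
`derive_seed()` fans a single pipeline seed out to per-stage seeds by
hashing the stage name, so stages are reproducible independently of
execution order.

## Expression filtering, clustering and module naming

Genes are retained when CPM ≥ 2 in at least 3 samples — the criterion that
defines the filtered microglial gene universe. Clustering operates on
genes as rows with per-sample z-scores of log2(CPM + 1) as features,
Euclidean distance, `stats::kmeans` with 25 restarts under a fixed seed.
The log2(CPM + 1) transform is a package choice: the clustering input
scale is conventionally unstated in this literature, and log-scale
z-scores make module shifts comparable across expression magnitudes.

Modules are named mechanically by the sample group in which the cluster
centroid is maximal: E17/P7 Saline → IM, E17/P7 MIA → MIA-IM, P20 → JM,
P60 Saline MG-REP → REP-AM, other P60 → AM. This reproduces the
age/condition-enrichment naming without manual curation. One consequence
visible on synthetic data: flat background genes attach to whichever
centroid lies nearest the origin (typically the smallest module), so that
module's size exceeds its planted count while the partition identity
(module sizes sum to the filtered-gene count) always holds.

**Elbow selection.** `select_k_elbow()` returns the k maximising the
second difference of log(WCSS) — the curvature of the *relative* WCSS
drop. A raw second difference was considered and rejected: on convex WCSS
curves with unequal cluster sizes it always peaks at k = 2 regardless of
the true cluster number, because early splits remove geometrically larger
absolute variance. The log form scores each split by its proportional
variance reduction, picks the bend where proportional gains collapse
(k = 5 on default synthetic data), and still selects k = 2 on a toy curve
like (100, 40, 38, 37). A curve with no positive log-curvature (e.g.
linear or geometric WCSS) has no elbow; the smallest candidate bend is
returned with a warning.

## The simplified NB exact test

`nb_exact_test()` is a deliberately simple two-group exact test, not a
reimplementation of quasi-likelihood GLM machinery (externally computed DE
tables can be injected through `read_de_table()`):

1. counts are rescaled to the geometric-mean library size and rounded
   (total-count normalization);
2. a single common dispersion is estimated by the method of moments,
   pooling within-group variances across genes by regressing excess
   variance on squared mean through the origin, with the sampling variance
   of the mean removed from the denominator (an uncorrected denominator
   biases the estimate low at n = 3 + 3 and makes the test
   anticonservative);
3. for each gene the two group sums are modelled as NB with size scaled by
   replicate number, and the two-sided p-value is the total probability of
   all splits of the gene's count sum no more likely than the observed one.

Under a pure null (both groups NB with mu = 100, phi = 0.1, 2000 genes)
the realised type-I error at alpha = 0.05 is within 0.04–0.06 and the
p-value distribution is approximately uniform. Known limitation:
total-count normalization is biased when differential expression is
asymmetric and abundant — shifted genes inflate their group's library and
drag null genes the other way. Trimmed-mean normalization exists for
exactly this reason and is intentionally out of scope here.

## Cross-species overlap enrichment

The background is built from a strictly one-to-one ortholog map (pairs
ambiguous on either side are dropped): human lists are restricted to genes
with mouse orthologs and mapped into mouse identifier space (mouse is the
measurement space, so mapping human→mouse avoids re-mapping every module),
mouse lists are restricted to genes with human orthologs, and the
background is the union of the two filtered universes. Overlap p-values
are the hypergeometric upper tail P(X ≥ m) including the observed point
(the one-tailed Fisher convention); percent overlap uses the module as
denominator.

Permutation verification replaces one list by equal-size uniform draws
from the background and uses the add-one estimator
p = (b + 1)/(n_perm + 1). The estimator never returns 0 — an observed
statistic beating all 100,000 permutations reports 1/100,001, i.e.
p < 0.00001 — and Bonferroni correction across companion tests is applied
on top, with the raw value always retained. Because the overlap statistic
is integer-valued, its permutation p-values are discrete; uniformity under
the null is only approximate and improves with the spread of the overlap
distribution (the calibration test uses 2000-gene sets in an 8000-gene
background for this reason).

**Connectedness.** The scalar network statistic is the mean edge weight
over all unordered within-list pairs. This is an explicit package
definition — "overall connectedness" has no standard operational form —
with a sum-weight alternative exposed via `statistic = "sum"`; the mean
form is size-comparable across lists, which matters only for
interpretation since the permutation test conditions on list size either
way.

## 3D morphometry

**Spine subtypes** are assigned with precedence stubby → mushroom →
filopodia → thin: no neck is unambiguous; a head ≥ 0.6 μm defines mushroom
before neck length is consulted (head-driven classes outrank length-driven
ones in standard spine taxonomies); a neck > 3 μm then defines filopodia;
"head and neck < 3 μm" is read as the *combined* extent defining thin.
Geometry at exactly 3.0 μm combined extent (or beyond it with a small head
and short neck) matches no rule; it falls back to thin with a boundary
warning rather than erroring mid-pipeline.

**Interactions.** Distances use the Pythagorean theorem on the anisotropic
voxel grid (default 0.04 × 0.04 × 0.3 μm): for voxel displacement
(di, dj, dk), d = sqrt((di·sx)² + (dj·sy)² + (dk·sz)²). The z-plane
separation is |dk| of the minimizing cloud point, which makes the class
radii and plane counts mutually consistent: 0.3 = 1 × 0.3,
0.9 = 3 × 0.3, 1.5 = 5 × 0.3 (asserted by `validate_config()`). Class
boundaries are inclusive (≤), a choice the rules leave open. Coverage of
the spine head is measured on 36 angular bins (10° resolution) around the
in-plane head circle, each bin counting as covered when a microglial point
lies within the 0.3 μm contact radius; "surrounding at least half the head"
therefore means coverage ≥ 0.5. In the synthetic pipeline, head centres
and cloud points are exact geometric coordinates snapped to the voxel
grid; intensity-based anchoring of real image stacks is out of scope.

**Arbor morphometry.** Branch order is centrifugal: soma-adjoining
branches are order 1 and the order increments at each branch point. Sholl
profiles count sphere crossings analytically per segment (one crossing
when endpoints straddle the sphere, two when both endpoints lie outside
but the closest approach dips inside), which matches a dense-resampling
oracle without discretization error. Convex hull volume uses an
incremental 3D hull written in-package; coplanar inputs return volume 0
with a warning. SWC input follows the usual convention: 1-based ids,
parent −1 for the root, type 1 soma, coordinates in μm.

## Fate mapping

Demographics are the fractions of BrdU⁺EdU⁻, BrdU⁺EdU⁺ and BrdU⁻EdU⁺
cells among *labelled* IBA1⁺ cells — double-negative cells are excluded
from the denominator, per the normalization these experiments report; an
all-IBA1⁺ denominator is available for sensitivity analysis. A zero
denominator is flagged as undefined, never reported as 0. Group summaries
aggregate sections within animal first and animals within group second,
avoiding pseudo-replication from unequal section counts; section-level
s.e.m. is reported alongside. The generator's exact mode allocates
round(n·f) cells per class with largest-remainder correction, giving
deterministic fixtures.

## Correlation surfaces

`spearman_matrix()` computes Spearman's ρ with average ranks for ties and
pairwise deletion — within-cell comparisons across modalities have unequal
n, so each pair uses its own complete observations (minimum 3). Two-sided
p-values use the t-approximation t = ρ·sqrt((n−2)/(1−ρ²)). Constant
features are flagged undefined rather than zeroed. No multiple-testing
correction is applied to the surface by default, matching per-cell
starring conventions; `export_surface(bonferroni = TRUE)` switches it on.
Rank-based ρ with its own p-value is used throughout, including for the
significance mask — mixing a rank correlation with a product-moment
p-value, as figure legends in this literature sometimes do, is not
reproduced.

## Problem sizes and run times

The default synthetic transcriptome is 1748 genes × 30 samples (planted
modules at one tenth of observed sizes), chosen so that the full test
suite completes in about a minute and the acceptance script in seconds
while every calibration property (ARI ≥ 0.9 module recovery, elbow at
k = 5, NB type-I error, permutation uniformity) is measurable with
adequate precision. Permutation counts default to the study values
(10,000 overlap, 100,000 network) in the acceptance script and to smaller
values in the interactive pipeline demo.

## Known limitations

* Total-count normalization biases the exact test under abundant
  asymmetric differential expression (see above).
* The connectedness statistic is a package definition, not a community
  standard; results depend on it only through the permutation reference.
* Coverage at 10° angular resolution quantises the ≥ ½ criterion by
  ±1/36.
* The synthetic generator's modules are disjoint and its background flat;
  real transcriptomes have overlapping programmes and correlated noise,
  so real-data ARI will be lower than the near-perfect recovery seen
  here.
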