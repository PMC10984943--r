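---
title: "Spatial niches and EcoCellTypes from deconvolved spot data: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial niches and EcoCellTypes from deconvolved spot data: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and data model

`ectcraft` starts where spatial deconvolution ends. Its input is the per-spot
cell-type abundance matrix a tool such as cell2location estimates for a Visium
section (non-negative posterior-quantile values, one row per 55 µm spot, one
column per cell type), together with spot coordinates in µm and, optionally,
pathologist annotation polygons. From these it builds:

1. **pseudo-single-cell maps** — integer cells placed inside spots;
2. **distance statistics** between cell types and Shannon diversity;
3. **spot annotations** transferred from polygons;
4. **cross-section niches** — communities of spots with similar cell-type
   composition, found jointly over many sections;
5. **EcoCellTypes (ECTs)** — groups of cell types whose niche-enrichment
   profiles co-cluster, i.e. cell types that co-occur spatially;
6. **cohort stratification and survival analysis** on ECT fractions derived
   from bulk deconvolution.

Coordinates follow the image convention (y grows downward) because Visium
exports are image-registered; the unit is µm throughout.

# Pseudo-single-cell maps

Deconvolution abundances are real-valued. We discretize them by rounding *up*
per cell type and *down* for the declared cancer cell types. Rounding cancer
abundances down counters the tendency of deconvolution to smear the dominant
malignant signal into neighbouring spots, while rounding sparse stromal and
immune signals up preserves rare types; the published analysis this package
follows additionally adjusted the rule against a pathologist's reading of the
H&E image, a manual step we deliberately replace with the pure ceiling/floor
rule so results are reproducible. Exact integers are left unchanged
(`ceiling(n) = n`), so zeros stay zero.

Each counted cell is drawn at its spot centre plus a uniform offset within a
disc of radius 40 µm (inside the 55 µm spot footprint). The reference analysis
states only "a jitter of 40 µm"; we chose a *radial-disc* jitter, with 40 µm
as the radius, because it is isotropic. Under it the distance of a cell to its
spot centre has mean 2r/3, which the tests check. Placement is seeded and
deterministic.

Jitter adds up to 40 µm of positional noise to every pseudo-cell, which is
below the spot pitch (100 µm); nearest-distance statistics computed from the
maps are therefore spot-resolution statistics, not subcellular ones.

# Distances, diversity, annotation transfer, enrichment

For each pseudo-cell and each *other* cell type present in the same section we
keep the distance to the nearest cell of that type. Sections are never pooled
when computing distances; pooling happens only when medians are taken for
ranking (unweighted over all sections' rows, following the stated method).

The Shannon index is `-sum p log p` (natural log) over the positive parts of a
renormalized composition; it is maximized by the uniform composition.

Annotation polygons are transferred to spots on a **majority-area** basis with
one exception applied *first*: if the cancer compartment covers more than 30%
of the spot disc, the spot is labelled cancer regardless of the majority. The
spot is modelled as a disc of the declared spot diameter (Visium spots are
circular); only labelled area competes in the majority rule, and ties go to
the lexicographically smallest label. Because no polygon-clipping library is
part of the package's dependency set, area fractions are computed by a
deterministic equal-area "sunflower" quadrature of 400 points over the spot
disc with ray-casting point-in-polygon; the worst-case area error of this
quadrature (~1/400) is far below the 30% decision threshold and the test suite
exercises polygons cut near the threshold.

Compartment enrichment follows the one-versus-all design: per compartment, the
per-section proportion of a state among its parent type's cells is compared
with the pooled per-section proportions of all other member states by a
two-sided Wilcoxon rank-sum test. The test is computed in-package: exact by
exhaustive enumeration of group assignments when the combined sample size is
at most 20 (ties handled exactly), otherwise the normal approximation with tie
and continuity correction. Raw p values are reported (the reference analysis
reports exact p values); a Benjamini–Hochberg column is emitted alongside. A
pooled Fisher's exact test over the state-by-compartment count table is also
returned.

# Niche identification

Spot compositions live on the simplex, so Euclidean machinery is applied after
an **isometric log-ratio (ILR)** transform. A fixed Helmert-type sequential
binary contrast basis is used: any orthonormal basis yields an isometric
embedding (clustering is basis-invariant), and fixing it makes runs
reproducible. ILR is undefined at zero, and deconvolution outputs contain
near-zeros; we add a pseudocount of `1e-3` times the row mean before
normalizing, which keeps the transform invariant to the overall scale of a
spot's abundances. Whether the original analysis transformed proportions or
raw abundances is not documented; proportions are used here because the ILR is
defined on compositions.

Sections are batches. The **batch-balanced kNN graph** connects each spot to
its `k = 3` nearest neighbours within *every* section (the default of the
bbknn tool the reference analysis ran with default parameters), then
symmetrizes by union. A per-section multiplicative, per-cell-type batch factor
is exactly a constant translation of that section's spots in ILR space, which
is the geometry this graph construction absorbs.

Communities are found by **Leiden** optimization of RBConfiguration modularity
at resolution 0.6 (the documented resolution), with 10 seeded restarts keeping
the best-quality partition; labels are renumbered by descending size. Whether
the original run used the modularity or CPM objective is not documented;
RBConfiguration modularity was chosen and is recorded in the run manifest.

A practical regime note: with `B` sections each spot has ~`3(B+1)` incident
edges. For the study design (17 sections) the graph is dense enough that
modularity optimization is stable; on toy datasets with 2–3 sections the
communities become sparse internally and can split spuriously, so the test
suite raises `k_within_batch` there. This is a property of sparse modularity
optimization, not of the niche model.

**Niche mapping to new sections** is deliberately simple: new spots are
ILR-transformed with the model's basis and assigned the nearest niche centroid
(Euclidean), with the assignment distance reported as a confidence proxy. The
reference analysis used the label-transfer machinery of a trained
deep latent-variable model for this step; that model is out of scope here, and
the centroid rule is validated only against synthetic ground truth
(held-out-spot agreement).

# EcoCellTypes

The niche-mean composition matrix (niches x cell types; spots pooled
unweighted across sections) is centred and scaled *per cell type* — in the
published heatmap, cell types are rows and "values were centered and scaled by
rows" — then cell-type profiles across niches are clustered agglomeratively
with Euclidean distance and Ward.D2 linkage. The number of groups can be fixed
(`k = 10` reproduces the published count) or chosen automatically by maximal
mean silhouette over k in [2, min(15, D-1)]; how the published 10-group cut
was chosen is not documented, so both modes are provided and "auto" is the
default. ECT ids follow dendrogram leaf order.

ECT fractions for bulk-deconvolved samples are sums of member cell-type
fractions, preserving row sums exactly.

# Cohort analysis

Samples are stratified by hierarchical clustering of ECT-fraction vectors
under **correlation distance** (1 - Pearson, the default semantics of the
heatmap tool named in the reference methods) with Ward.D2 linkage, cut at
k = 4 subgroups by default. Constant rows, for which correlation is undefined,
are assigned post hoc to the nearest subgroup centroid with a warning.

Kaplan–Meier curves use the product-limit estimator computed in-package, and
the k-sample **log-rank** statistic is assembled directly from the
observed-minus-expected event counts with the hypergeometric
variance-covariance at each distinct event time, so the test is auditable line
by line; the test suite cross-checks it against the standard `survival`
implementation. With no events the result is an explicit "no events" record
rather than a statistic.

Median stratification assigns ties at the median to "high" (with odd n the
median sample is "high"); the convention is undocumented in the reference and
fixed here for symmetry across analyses. The two-marker risk rule is
`low risk = protective >= its median AND adverse < its median`; the reference
figure defines low risk as "high Detox-iCAF and low TGFβ-myCAF content"
without stating the cutoffs, and the median is inferred from the adjacent
single-marker analyses. Multivariate Cox models delegate to
`survival::coxph` with Efron tie handling — a standard estimator contract, not
part of this package's novel computation.

# The synthetic generator

No patient data ship with the package; every downstream stage is exercised on
a generator whose defaults are the study design: 17 sections, 2,000 spots per
section on a 100 µm-pitch hexagonal lattice of 55 µm spots, 37 cell types, 11
niches, 10 ECT blocks, an expected 15 cells per spot (the deconvolution
`N_cells_per_location` setting), moderate per-section batch shifts
(log-normal, sd 0.3) and a Dirichlet precision of 150 around niche centres.
Design choices, in the package's own words:

- **Spatial layout**: niches are nearest-seed Voronoi domains (2 seeds per
  niche per section) with boundary raggedness controlled by jittering spot
  positions before seed assignment (sd = pitch / `spatial_smoothness`,
  default 4). Real niches are contiguous with irregular boundaries; no
  generative model for their shapes is documented, so the smoothness knob is a
  free parameter, not an estimate.
- **Compositions**: each niche has a compositional centre; spot compositions
  are Dirichlet draws around it, scaled by a Gamma-distributed total
  (shape 25, mean 15 — i.e. ~20% CV) and a per-section per-type log-normal
  batch factor. Abundances are non-negative reals, emulating posterior
  quantiles, not counts.
- **ECT blocks**: cell types in a block share a block-level niche-enrichment
  profile (plus small per-type jitter, sd 0.15). Block profiles are
  rejection-sampled to pairwise |correlation| <= 0.4 and a minimum norm: the
  planted block structure *is* the ground truth, and without this constraint
  two blocks can coincide (or a block can be too weak to survive per-type
  scaling), making the planted count unrecoverable by any method.
- **Annotations**: each niche maps to one of the five compartment labels
  (peritumor stroma, intratumor stroma, cancer cells, lymphocyte aggregates,
  normal ducts and lobules) and every spot is covered by its hexagonal lattice
  cell, so the true compartment of a spot is recoverable by the transfer rule.
- **Cohorts**: sample compositions are Dirichlet draws around one of four
  archetype centres planted at the *ECT level* (a Dirichlet over blocks with
  one shared within-block split) — archetypes planted at the cell-type level
  can collide after ECT aggregation, which would defeat ECT-based
  stratification by construction. Survival is exponential with log-hazard
  linear in the planted ECT fractions and independent exponential censoring
  (default rate 0.08 per unit time against a baseline event rate of
  log(2)/5), the minimal model that supports Cox parameter-recovery tests.

What the generator does *not* emulate: gene-level noise and deconvolution
error structure (spatially correlated mis-assignment between transcriptionally
similar types), tissue morphology, holes and tears, spot-level quality
gradients, or clinical covariate confounding. Passing recovery tests therefore
demonstrates the pipeline's correctness and its behaviour under the study's
compositional/batch design — not performance on real tissue.

# Replication design and problem sizes

The end-to-end checks run the full study geometry: 34,000 spots across 17
sections, 37 cell types. The dataset and its deterministic kNN graph are
generated once per base seed; the 10 replicate seeds vary the stage that is
actually stochastic — Leiden restarts for the niche count, independent
generator draws for the ECT count (whose clustering is deterministic given the
data). Smaller fixtures (2–4 sections, 150–300 spots) are used for unit tests;
example-based tests that presume "high separation" use seeds whose realized
niche-centre separation satisfies that premise.

# Numerical choices and degenerate inputs

- Pseudocount `1e-3 x` row mean before ILR; ILR of a two-part composition
  (p, 1-p) is `log(p/(1-p))/sqrt(2)`, which the tests pin to closed form.
- kNN ties are broken by first index; Leiden restarts derive their seeds from
  the user seed, so runs are reproducible end to end.
- Constant columns in scaling become zero with a warning; a single niche
  cannot be scaled (error).
- Rank-sum enumeration cutoff at combined n = 20 (choose(20,10) = 184,756
  assignments); beyond that, normal approximation with tie correction.
- Log-rank with a singular variance matrix (e.g. identical groups) falls back
  to a pseudoinverse; identical groups give chi-square 0, p = 1.
- Degenerate medians (all values equal) are errors for median and risk
  stratification, not silent single-group outputs.
- `n_niches > spots_per_section`, negative censoring rates, unmapped niche
  ids, unknown cancer types, and cell-type mismatches in niche mapping are
  rejected with named errors.

# Known limitations

- The centroid-based niche mapper ignores within-niche covariance; a niche
  with elongated ILR geometry may lose boundary spots to its neighbours.
- The annotation quadrature is approximate (±~0.25% area); polygons thinner
  than ~3 µm at a spot may be missed.
- The Wilcoxon normal approximation is used above n = 20 even under heavy
  ties; for small-section studies the exact path covers all realistic sizes.
- Niche detection inherits the resolution-dependence of modularity
  optimization: the recovered community count equals the planted count under
  the study design, but on sparser graphs (few sections) the same resolution
  can oversplit.
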