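# ectcraft

Downstream spatial analysis of **deconvolved spatial transcriptomics**: from
per-spot cell-type abundance estimates (e.g. cell2location output on Visium
sections) to pseudo-single-cell maps, cell-type distance statistics,
cross-patient **spatial niches**, **EcoCellTypes** (groups of spatially
co-occurring cell types), and ECT-based cohort stratification with survival
analysis. A synthetic multi-section generator with known ground truth stands
in for patient data, so the whole pipeline is installable and testable
offline.

Intended users: computational biologists who already ran spot deconvolution
and want the niche/co-occurrence/survival layer on top of it, plus a
simulation harness to validate that layer.

## The methods in brief

- **Pseudo-single-cell maps.** Abundances are discretized — `ceiling` per cell
  type, `floor` for declared cancer types — and each counted cell is placed at
  its spot centre plus a uniform draw from a 40 µm disc (55 µm spots).
- **Distance statistics.** For each pseudo-cell and each other cell type in
  the same section, the nearest-neighbour Euclidean distance; types are ranked
  by median distance to an anchor type (typically cancer cells). Shannon
  diversity `H = -Σ p·ln p` summarizes per-sample composition.
- **Annotation transfer.** Pathologist polygons (GeoJSON) are transferred to
  spots by majority covered area, except that >30% coverage by the cancer
  compartment assigns the cancer label outright. Compartment enrichment of
  cell states uses a two-sided Wilcoxon rank-sum "one versus all" on
  per-section proportions (exact by enumeration for n ≤ 20).
- **Niches.** Spot compositions are mapped to unconstrained coordinates by the
  isometric log-ratio transform (fixed Helmert-type orthonormal basis,
  pseudocount of 1e-3 × row mean), connected in a batch-balanced kNN graph
  (k = 3 within every section), and clustered with Leiden at resolution 0.6.
  New sections are mapped by nearest niche centroid in ILR space.
- **EcoCellTypes.** The niche × cell-type mean-composition matrix is centred
  and scaled per cell type; cell-type profiles are clustered with Ward.D2 on
  Euclidean distances; the cut is fixed (`k = 10` reproduces the published
  count) or chosen by maximal mean silhouette.
- **Cohorts.** ECT fractions (sums of member cell-type fractions) feed
  correlation-distance/Ward.D2 patient subgrouping (k = 4), Kaplan–Meier +
  log-rank (computed from observed−expected counts with hypergeometric
  variance), median and two-marker risk stratification, and multivariate Cox
  (delegated to `survival`).

See `vignettes/ectcraft-methods.Rmd` for assumptions, parameter defaults,
numerical choices and the limits of what the synthetic tests demonstrate.

## Worked example

```r
library(ectcraft)

cfg <- sim_config(n_sections = 4, spots_per_section = 500, n_cell_types = 12,
                  n_niches = 5, n_ect_blocks = 4, seed = 7)
sim <- generate_sections(cfg)

model <- fit_niche_model(sim$sections, k_within_batch = 10, seed = 1)
max(model$niche_labels)
#> [1] 5
table(model$niche_labels)
#>   1   2   3   4   5
#> 519 415 415 379 272

m <- niche_composition(model$niche_labels, sim$sections)
ect <- cluster_ect(scale_composition(m), k = "auto")
ect$n_ect
#> [1] 4
split(names(ect$membership), ect$membership)[3]
#> $`3`
#> [1] "Cancer cells" "CellState04"  "CellState07"

cm <- build_cellmap(sim$sections[[1]], cancer_types = "Cancer cells", seed = 1)
nrow(cm)
#> [1] 11351
head(rank_by_median_distance(nearest_distance_table(cm), "Cancer cells"), 3)
#>   reference_type median_distance rank
#> 1    CellState07        98.87388    1
#> 2    CellState04       129.03074    2
#> 3    CellState09       170.25849    3

co <- generate_cohort(cfg, 300, effect = c(-3, 0, 3, 0))
ef <- ect_fractions(co$table[, cfg$cell_types], co$truth$ect_membership)
res <- km_logrank(co$table$time, co$table$event, median_stratify(ef[, "ECT1"]))
sprintf("log-rank chisq = %.2f, p = %.3g", res$chisq, res$p_value)
#> [1] "log-rank chisq = 0.91, p = 0.341"
```

Reading: the five planted niches are recovered exactly (adjusted Rand index
1.0 against the generator's ground truth), the four planted co-occurrence
blocks come back as four EcoCellTypes, the cell types sharing the cancer
cells' block are ranked closest to cancer cells in physical distance
(medians ~99–129 µm at a 100 µm spot pitch), and a median split on an ECT
carrying no planted hazard effect shows, as expected, no significant survival
separation.

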