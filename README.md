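# cytofnet

Phenotype clustering and correlation-network ("immuno-interactome")
analysis for case-control mass cytometry cohorts.

Deep immunophenotyping studies of chronic disease — the motivating case is
heart failure (HF) versus healthy controls (HC), with the HF group split by
left-ventricular ejection fraction into preserved (HFpEF) and reduced
(HFrEF) subgroups — measure dozens of markers on hundreds of thousands of
single cells per subject with CyTOF. Two questions drive the analysis:

1. **Which immune cell subsets change in abundance?** Cells are pooled,
   clustered into phenotype *nodes*, and each subject's node frequencies
   are compared between groups.
2. **How does the *architecture* of the immunome change?** Across-subject
   correlations between node frequencies define a signed network whose
   topology (modularity, centralization, edge density, signed edge
   balance) is compared between cohorts.

`cytofnet` implements that pipeline end to end in tidyverse style (tibbles
in, tibbles out), together with a Gaussian-copula synthetic-cohort
generator with full ground truth, so every stage is testable without any
instrument data.

## Method summary

For each sample (subject × antibody panel) with raw intensity matrix
`X` (cells × markers):

- **Transform** — `y = asinh(x / c)` with cofactor `c = 5`.
- **Batch normalization** — each marker column is standardized to mean 0,
  sd 1 within each acquisition batch (cells pooled across the batch's
  samples, so between-sample abundance signal survives).
- **Downsampling** — each sample is reduced to 10,000 cells by seeded
  uniform sampling without replacement (short samples kept whole).
- **Clustering** — k-means (k-means++ seeding, restarts, lowest WCSS wins)
  on cells pooled across all subjects of a panel; `k` chosen by the elbow
  method, operationalized as the point of maximum perpendicular distance
  to the chord of the (min-max normalized) WCSS curve.
- **Annotation** — per-node scaled median phenotypes (`(median − mean) / sd`
  across nodes, per marker) gated by an ordered marker-pattern table
  (e.g. NK: CD3−CD56+; MAIT: CD3+Vα7.2+CD161+; Treg: CD3+CD4+CD25+FOXP3+;
  monocyte/DC: CD3−CD19− with any of CD14/CD16/CD11c+).
- **Differential abundance** — per node, a two-sided Wilcoxon rank-sum
  test on subject frequencies (exact by enumeration for small untied
  groups, otherwise normal approximation with midranks, tie-corrected
  variance and continuity correction); raw `p < 0.05` by default,
  Benjamini–Hochberg behind a flag.
- **Interactome** — T/NK node frequencies from panel 1 and B/monocyte-DC
  node frequencies from panel 2 are combined over the shared subjects;
  per cohort, Pearson correlations between node frequencies are
  thresholded at `|r| > 0.6` into a signed network, and the comparative
  property suite is computed: edge density `m / C(n,2)`, Freeman
  betweenness centralization `Σ(b_max − b_i) / [(n−1)²(n−2)/2]`, global
  transitivity `3·triangles / triples`, Newman–Girvan modularity
  `Q = Σ_c [m_c/m − (d_c/2m)²]` under deterministic greedy agglomerative
  community detection, average shortest-path length over reachable pairs,
  signed edge counts, per-lineage mean degree, and intra- vs
  inter-lineage edge classification.

The synthetic generator plants: subject-level subset frequencies from a
Gaussian copula on the logit scale (closed to the simplex per panel, with
cohort-specific correlation structure and log-fold-change shifts), cells
as Gaussian mixtures in arcsinh space mapped back to the raw scale, and
additive per-batch marker shifts — so preprocessing, clustering,
differential testing and network recovery can each be validated against
known truth.

## Worked example

Simulate a two-panel cohort at the study's design (36 markers per panel,
19 shared; HC n=18, HF n=32 with a 14/14/4 EF split), preprocess, cluster
into nodes, test abundance, and compare the cohort networks:

```r
library(cytofnet)
library(dplyr)

spec <- cohort_sim_spec(n_cells_per_sample = 1000, seed = 1)
sim  <- simulate_cohort(spec)
sim
#> Synthetic CyTOF cohort: 50 subjects, 2 panels, 1e+05 cells
#>   cohort subtype     n
#> 1 HC     <NA>       18
#> 2 HF     HFmrEF      4
#> 3 HF     HFpEF      14
#> 4 HF     HFrEF      14

cells <- preprocess_cohort(sim$cells, cofactor = 5, target = 1000, seed = 1)
cl    <- lapply(cells, cluster_panel, k = 16, seed = 1)
freq  <- lapply(names(cl), \(p)
  frequency_matrix(cl[[p]]$model$assignments, sim$sample_sheet, cl[[p]]$nodes))
names(freq) <- names(cl)

differential_nodes(freq$P1, groups = c("HC", "HF")) |>
  filter(significant) |>
  select(node_id, lineage, median_control, median_case, p_value, direction)
#>   node_id lineage median_control median_case    p_value direction
#> 1 P1_N01  CD4T            0.0865      0.0595 0.00212    reduced
#> 2 P1_N04  CD8T            0.061       0.0745 0.0453     expanded
#> 3 P1_N05  CD8T            0.034       0.048  0.0185     expanded
#> 4 P1_N06  CD8T            0.02        0.009  0.000135   reduced
#> 5 P1_N07  CD8T            0.053       0.0355 0.0157     reduced
#> 6 P1_N08  CD4T            0.108       0.0765 0.00561    reduced
#> 7 P1_N12  NK              0.0315      0.0675 0.00000904 expanded
#> 8 P1_N15  NK              0.0455      0.077  0.0000527  expanded
#> 9 P1_N16  CD4T            0.0665      0.0405 0.00243    reduced
```

Each row is one phenotype node: its median frequency in controls and
cases, the rank-sum p-value and the direction of change. Here the
generator's planted biology is recovered — cytotoxic/inflammatory NK
nodes expand in HF while CD4 memory nodes contract.

```r
comb <- combine_panels(freq$P1, freq$P2)   # T/NK from P1, B/MonoDC from P2
network_compare(comb, cohorts = c("HC", "HF"), threshold = 0.6)
#>   property                       HC      HF
#> 1 edge_density               0.0554  0.0769
#> 2 centralization_betweenness 0.0855  0.0606
#> 3 modularity                 0.674   0.269
#> 4 average_path_length        2.25    1.62
#> 5 no_neg_edges               6       6
#> 6 no_pos_edges               12      19
```

The healthy cohort's network is strongly modular (Q = 0.67: lineage
blocks correlate internally) and more centralized, while the disease
cohort's planted cross-lineage "inflammatory axis" produces one dispersed
blob (Q = 0.27) — the qualitative architecture contrast the interactome
stage is built to detect.

`run_pipeline(pipeline_config(...))` executes all stages behind one
(optionally YAML) configuration and writes every table (TSV), edge lists,
GraphML networks, a JSONL log and a markdown report into a run directory;
reruns with the same config and seed are byte-identical.

## Package layout

- `R/simulate.R`, `R/correlations.R`, `R/panels.R` — synthetic cohorts,
  planted correlation presets, panel/subset/gating defaults
- `R/preprocess.R` — arcsinh, batch normalization, downsampling
- `R/clustering.R` — k-means nodes, elbow selection, phenotypes, gating
- `R/abundance.R` — frequency matrices, rank-sum test, differential nodes
- `R/network.R` — panel combination, signed networks, property suite,
  greedy community detection
- `R/pipeline.R` — configuration, orchestration, report
- `R/fcs.R`, `R/io.R` — FCS 3.0 / CSV cohort round-trip
- `vignettes/methods.Rmd` — the modeling assumptions, parameter choices
  and limitations in detail
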