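---
title: "Methods: from single-cell marker matrices to cohort interactomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from single-cell marker matrices to cohort interactomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cytofnet` turns per-sample CyTOF cell-by-marker matrices into (i) a
differential-abundance table over phenotype nodes and (ii) a per-cohort
signed correlation network with a comparative topology suite. This
vignette records the model, the parameter choices, and the places where
the design was genuinely open — and what the synthetic tests do and do
not establish about real data.

## 1. Preprocessing

**Arcsinh transform.** Raw dual-count intensities are mapped through
`asinh(x / cofactor)` with `cofactor = 5` (dimensionless divisor on the
instrument's count scale), the mass-cytometry convention: linear near
zero, logarithmic for large counts, defined at zero. The transform is
strictly monotone and inverted exactly by `cofactor * sinh(y)`
(round-trip tested to 1e-10).

**Batch-wise scale normalization.** "Scale normalization" is read as
per-batch, per-marker standardization of the transformed values to mean
0, sd 1, pooling all cells of a batch. Two alternatives were rejected:
per-sample standardization would erase the between-sample abundance
signal that the downstream stages exist to measure, and location-only
centering would leave scale (gain) batch effects in place. Pooled
standardization is idempotent, removes any additive per-batch marker
shift exactly (the generator plants exactly this kind of shift, giving a
machine-precision unit test), and leaves constant columns at zero rather
than dividing by zero. Panels are normalized separately: they are
stained and acquired separately and share only a subset of markers.

**Downsampling.** Each sample is reduced to `target = 10000` cells by
seeded uniform sampling without replacement. Samples below the target
are kept whole with a warning — data are never fabricated, and dropping
short samples is a cohort-level decision the caller should make
explicitly. Row order within a sample is preserved so the operation is a
strict subset.

## 2. Phenotype nodes

**k-means.** Cells of one panel are pooled across all subjects and
cohorts before clustering, so node identities are shared across cohorts;
cross-cohort frequency comparisons and cohort networks over a common
node set require this. Initialization is k-means++-style careful
seeding; `n_restarts = 10` restarts of Lloyd's algorithm (cap 50
iterations) are run and the restart with the lowest within-cluster sum
of squares (WCSS) wins. All stochastic steps take explicit seeds;
repeated fits are identical.

**Elbow selection of k.** The WCSS curve over `k_grid` is min-max
normalized on both axes and the selected k maximizes the perpendicular
distance to the chord joining the curve's endpoints. Normalization
matters: in raw units the distance is dominated by the WCSS scale and
the criterion degenerates toward the grid midpoint. A near-linear curve
(maximum distance < 1e-8 in normalized units) triggers a warning and the
smallest interior k, making the degenerate case explicit rather than
arbitrary. The default grid is 10-120 in steps of 10; the published
preset for this study design is k = 80 per panel.

**Phenotypes and gating.** Node phenotypes are per-marker medians over
member cells; for display and gating they are scaled across nodes
(subtract the per-marker mean across nodes, divide by the sd across
nodes). A marker is called positive in a node when its scaled median
exceeds 0, i.e. the node sits above the across-node average. Lineage
assignment applies an ordered rule table (Treg before MAIT before CD4T
before CD8T, so the more specific phenotypes win; then NK, B,
monocyte/DC with an any-of clause over CD14/CD16/CD11c; unmatched nodes
are "other"). Rules referencing markers absent from a panel error,
except that an any-of set is restricted to the panel's markers (the rule
is dropped only if none remain). Gating is a pure function of phenotypes
and gates. Caveat: with very few nodes the across-node scaling makes
uninformative markers' scaled medians pure noise of magnitude ~1, so
positivity calls are only meaningful at realistic node counts (roughly
k ≥ 5).

## 3. Differential abundance

Subject-level node frequencies (cells of subject in node / cells of
subject in panel; rows close to 1 by construction) are compared between
groups with a two-sided Wilcoxon rank-sum test implemented in the
package: exact p by complete enumeration of rank assignments when
`min(n, m) <= 8` and the pooled data are untied, otherwise a normal
approximation with midranks, tie-corrected variance and a 0.5 continuity
correction. The exact path is validated against an independent
enumeration oracle and against `wilcox.test` for every small group-size
combination. The default significance convention is raw `p < 0.05` with
no multiplicity correction, mirroring the analysis this package
reproduces across ~80 nodes per panel; Benjamini-Hochberg is available
behind `adjust = "BH"` and then drives the significance flag. Direction
("expanded"/"reduced" in the case group) is called from the median
difference.

## 4. The interactome

T-lineage and NK nodes from panel 1 and B and monocyte/DC nodes from
panel 2 are combined over the subjects present in both panels
(subjects missing a panel are excluded and logged). Per cohort, Pearson
correlations between node frequencies are computed (Spearman by config;
Pearson is the ecosystem default for this analysis); zero-variance
columns yield missing correlations, which never become edges. Edges
connect pairs with `|r| > 0.6`; the boundary is strict by default with
`strict = FALSE` giving `>=` — the source conventions disagree between
"greater than" and "0.6 or greater", so both are supported.

Topological metrics are computed on the unweighted, sign-blind graph;
signs are retained as edge attributes and summarized separately
(counts and percent negative):

- *Edge density* `m / C(n, 2)`.
- *Freeman betweenness centralization*: vertex betweenness by
  shortest-path counting with endpoints excluded, centralized as
  `sum(b_max - b_i)` over the star graph's maximum
  `(n-1)^2 (n-2) / 2` (star = 1, vertex-transitive graphs = 0).
- *Transitivity*: `3 * triangles / connected triples`; undefined (NA)
  without triples.
- *Average path length*: mean over unordered **reachable** pairs;
  thresholded networks are routinely disconnected and no convention is
  stated in the source, so unreachable pairs are excluded rather than
  imputed.
- *Modularity*: Newman-Girvan Q of the partition returned by a
  deterministic greedy agglomerative (CNM-style) maximization — merge
  the connected community pair with the largest gain, ties broken
  toward the smallest community indices, return the partition with
  maximal Q along the merge path; an edgeless graph gets the singleton
  partition with Q defined as 0. Because reported Q depends on the
  detection algorithm and the source does not name one, absolute Q
  values are not comparable across implementations; only contrasts
  computed with the same algorithm are interpreted.

Shortest-path machinery (betweenness, distances, transitivity) delegates
to igraph; centralization, Q, edge classification and the greedy
agglomeration are implemented here and verified against brute-force
oracles (all-pairs BFS, path-count betweenness, exhaustive
triangle/triple enumeration, direct Q formula) on random graphs with
n ≤ 12 to 1e-10.

## 5. The synthetic-cohort generator

The generator is first-class, tested code; its defaults are the study
conditions: two 36-marker panels sharing a 19-marker backbone, cohorts
HC = 18 and HF = 32 (HFpEF 14, HFrEF 14, HFmrEF 4), 20,000 cells per
sample, three acquisition batches (allocation round-robin, configurable
— the source does not state it), arcsinh cofactor 5.

**Frequencies.** Each subject's true subset proportions come from a
Gaussian copula: correlated standard-normal scores (cohort-specific
correlation matrix) scaled by `sigma_logit = 0.5`, shifted onto
`logit(base proportion) + cohort log-fold-change`, passed through the
logistic function and closed to the simplex within each panel. Closure
has two systematic consequences worth knowing: a common factor moving
all subsets together cancels entirely, and coherent blocks of subsets
anti-correlate with other blocks through the shared denominator. Both
shrink as subsets get smaller, which is why the default table has 30
small subsets (base proportions 0.04-0.14, echoing a real immunome's
many small nodes) rather than a few large ones. Residual attenuation of
a planted |r| = 0.8 is about 0.03-0.05 at this granularity. With exactly
two subsets, closure forces the two proportion columns into perfect
anti-correlation regardless of the planted copula — planted structure is
only expressible with several subsets.

**Cells.** Given proportions, per-subset cell counts are multinomial;
marker values are Gaussian around the subset's mean profile in
transformed space (positive markers at 3, negative at 0.2, dispersion
0.35 — separation/dispersion 8, comfortably above the ratio ≥ 6 regime
where k-means recovery is tested), plus the subject's batch shift, then
mapped to the raw scale by `5 * sinh(y)` and clipped at 0 (counts are
nonnegative; the clip slightly truncates the lower tail of negative
markers). This makes preprocess → cluster exactly invert the generative
model, up to sampling noise.

**Planted case-control biology.** Cohort shifts compose a case-group
effect (HF) with a subtype effect (e.g. HFpEF): cytotoxic/inflammatory
NK subsets, effector/exhausted CD8 subsets, immature B subsets and
conventional DCs expand in HF; an effector-memory CD4 subset, a memory
CD8 subset and classical monocytes contract; inflammatory MAIT, CD4 and
Treg subsets additionally expand in HFpEF relative to HFrEF.

**Planted architecture.** Correlation structures are factor models
(`R = LL' + diag`, PSD by construction, unit diagonal):

- *Modular (healthy-like)*: lineage blocks with within-block r = 0.8, of
  which a 0.2 share rides on a global factor (the global component is
  largely cancelled by closure but damps block-mass fluctuations and
  hence spurious closure-induced negative correlations); consecutive
  lineage blocks are joined through one *bridge* subset each, loading
  0.6 on both of its blocks' factors plus the global loading. The
  bridges matter: a single "hub" node cannot be strongly correlated with
  many mutually uncorrelated blocks — the unit-variance budget caps
  `sum(loadings^2)` at 1, so literal hubs are not positive semidefinite.
  A chain of dense modules joined by bridges yields both high modularity
  and high betweenness centralization, which is the architecture the
  network stage must detect.
- *Dispersed (disease-like)*: a cross-lineage "inflammatory axis" factor
  — the HF-expanded subsets load +0.8, the contracting subsets −0.8 —
  over weak residual lineage blocks (within 0.5). The axis survives
  closure (the two groups move oppositely), creating one dense
  cross-lineage blob with negative expanding-vs-contracting edges: low
  modularity, low centralization, mostly inter-lineage contacts.

The directional consequences (modular cohort: higher modularity and
higher centralization) are tested over 20 seeded frequency-level
replicates at the study's cohort sizes and hold in ≥ 18 of 20. The
negative-edge *share* contrast (disease > healthy) is planted in the
axis signs but is **not** robust at n = 18/32 sampling noise — sample
correlations cross the −0.6 threshold haphazardly at these n — so it is
reported descriptively but not asserted.

**What the generator does not emulate.** Doublets, beads, debris,
spillover, acquisition-time drift, non-Gaussian marker distributions
(real CyTOF is zero-inflated), cell-cell dependence within a sample, and
covariate structure (age, sex, comorbidity). Passing tests therefore
establish that the pipeline recovers *its own generative model's*
structure at realistic sizes — correctness of the machinery, not
robustness to everything real data does.

## 6. Problem sizes and determinism

The test suite runs in under a minute on one CPU: unit fixtures use
hundreds to a few thousand cells; the end-to-end smoke preset uses two
8-marker panels, 20 subjects, 500 cells per sample; the directional
suite uses frequency-level replicates (no cell synthesis). The
acceptance script runs the full 36-marker, 50-subject design at 2,000
cells acquired / 1,000 retained per sample with an elbow grid of
6-26 — about two minutes. These sizes are the package's chosen
desk-scale defaults for reproducible checking; the pipeline itself is
routinely run at 10,000 retained cells and k ≈ 80.

Every stochastic stage (proportion sampling, cell synthesis, batch-shift
draws, downsampling, k-means seeding, layout) takes an explicit seed
derived from one master seed; identical configuration and seed give
byte-identical tabular outputs, which the suite asserts via file
checksums.

## 7. Known limitations

- Node resolution couples to network topology: k far above the true
  subset count splits populations into sibling nodes whose near-perfect
  mutual correlation inflates modularity; k far below merges planted
  structure away. The elbow criterion lands near the effective subset
  count on generator output, but on real data k is a substantive choice.
- Average path length over reachable pairs only is not comparable
  between networks with very different fragmentation.
- The rank-sum exact path requires untied data; frequency ties (shared
  zeros at rare nodes) route even small samples to the approximation.
- Greedy agglomerative community detection is deterministic but greedy;
  its Q can trail other heuristics' by a small margin, and all reported
  Q values are algorithm-conditional.
- FCS support is a minimal 3.0 float32 writer/reader for this package's
  own round-trips, not a general FCS implementation; CSV is the default
  interchange format.
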