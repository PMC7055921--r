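---
title: "Quantifying the organization of lymphocytic infiltrates with neighborhood graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the organization of lymphocytic infiltrates with neighborhood graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lymphgraph)
```

## The problem

Tertiary lymphoid organs (TLOs) are ectopic lymphoid structures that arise at
sites of chronic inflammation: a compact core of CD20⁺ B cells surrounded by
a zone of CD3⁺ T cells. Distinguishing them — and their poorly defined early
stages — from ordinary lymphocytic infiltrates is clinically relevant in
transplant pathology, oncoimmunology and chronic lung disease, but visual
assessment is slow and observer-dependent. `lymphgraph` turns the question
into one about the spatial arrangement of typed points: given the coordinates
and phenotypes (T or B) of every lymphocyte in a region, detect contiguous
infiltrates and quantify how TLO-like each one is.

## The neighborhood graph model

All cell centers, irrespective of phenotype, are triangulated (Delaunay).
The triangulation itself connects everything to everything through arbitrary
distances, so edges are filtered by a contact criterion: **every side of a
triangle whose circumcircle radius is strictly smaller than a cutoff `t` is
kept**. This is the alpha-complex construction; the circumradius, not the
edge length, is the criterion, so a short edge between two otherwise isolated
cells (whose every triangle is huge) is correctly discarded. An edge incident
to both a qualifying and a non-qualifying triangle is kept — the rule is a
union over triangles, which is how "all sides of a qualifying triangle"
reads, and it makes the kept edge set monotone in `t`.

Connected components of the filtered graph are the **infiltrates**.
Components below `min_nodes` cells (default 10, roughly the smallest
structure a pathologist would outline) are discarded and counted in the log.
`t = 0` yields no infiltrates; `t = Inf` recovers the full, connected
Delaunay graph. Every output graph is a Delaunay subgraph, hence planar with
`|E| <= 3|V| - 6`.

### Choosing `t`

The default `t = 45` px at 0.253 µm/px corresponds to 11.385 µm between cell
centers — essentially direct cell contact for lymphocytes. When a different
scan resolution is supplied, the default converts that same physical distance
back to pixels, so resolution changes do not silently change the biology.
`calibrate_threshold()` reproduces the calibration procedure on your own
annotations: for each candidate `t` it checks, per pathologist-drawn outline,
whether the enclosed cells form a single connected component (edges to cells
outside the outline are ignored — connectivity is scored *inside* the
annotation), and picks the smallest `t` whose non-fragmentation fraction
reaches `target_fraction`. The default target of 1.0 demands that no
annotated infiltrate fragments; because annotated outlines are themselves
approximate, the report falls back to the best-approximation `t` (flagged)
when the target is never met, and always quotes the median length of kept
versus removed Delaunay edges at the chosen cutoff — kept edges should sit
near cell-contact distance, removed ones far above it.

## Edge labels and the organization score

With a designated phenotype `A` (B cells throughout, since the B core defines
a TLO), an edge is labelled `alpha` when its endpoints share a phenotype, and
`gamma_i` when it crosses phenotypes and its A endpoint participates in `i`
A–A edges. The per-infiltrate features are the node and edge counts, the
A-cell fraction, the A–A edge fraction, homogeneity `H = |E_alpha|/|E|`, the
clustering coefficient, degree statistics, mean pairwise distance, and the
organization score

$$\kappa(a) = \frac{|E| - |E_\alpha| - \sum_{j \le a} |E_{\gamma_j}|}{|E| - |E_\alpha|},$$

the fraction of inter-phenotype edges whose B endpoint has more than `a` B
neighbors. A mixed infiltrate scatters its B cells, so the B endpoints of
interface edges are B-isolated and κ stays near 0; a TLO concentrates its B
cells, so interface edges attach to the rim (or to interspersed T cells
inside the core) of a dense B cluster and κ approaches 1. Interspersed T
cells inside the B core — a normal feature of germinal centers — *raise*
rather than lower the score, which is the advantage of κ over plain B-cell
counts or clustering measures. The default orders are `a = 2` and `a = 5`,
the two used for classification.

Conventions worth knowing:

* A graph with no inter-phenotype edges has no TLO interface; κ is defined
  as 0 there and the value carries a `degenerate` attribute.
* The clustering coefficient is the average of local coefficients with the
  `1/|V|` prefactor taken literally: nodes with fewer than two neighbors
  contribute zero but stay in the denominator.
* Inputs with more than two phenotypes are rejected rather than guessed at;
  with exactly two, every inter-type edge has exactly one A endpoint, so the
  γ index is well defined.
* `|E_alpha|` counts same-type edges of *both* phenotypes; the A-only count
  is reported separately as `frac_alpha_B`.
* Mean pairwise distance is exact up to 5000 nodes; above that a seeded
  sample of 10⁶ pairs is used and the result is flagged.

## Classification

Infiltrates are classified into four organization classes — `T_CELL_AREA`,
`MIXED_UNSTRUCTURED`, `INTERMEDIATE`, `TLO_LIKE` — with a radial-kernel SVM
on five features: `n_edges`, `frac_alpha_B`, `frac_B`, `kappa_2`, `kappa_5`.
Several details are deliberate choices where the design was open:

* **Folds** are stratified by class with a fixed seed; 5 folds by default.
* **Scaling**: features span orders of magnitude (edge counts vs. scores in
  [0,1]), so they are z-scored — using training-fold statistics only, which
  the test suite enforces by checking that an outlier planted in a test fold
  cannot change its fold-mates' predictions.
* **Hyperparameters**: cost 1 and kernel width `1/p` on the standardized
  features (equivalently `1/(p · var)`); an inner grid search is available
  via `tune = TRUE` but off by default, since the default already separates
  the synthetic classes and silent tuning would hide what the features do.
* **Multiclass scheme**: one-vs-one voting for prediction; per-class metrics
  are then computed one-vs-rest, which is what a per-class table of
  TPR/TNR/PPV/NPV/ACC/F1 implies.
* **Aggregation**: metrics are computed in each test fold and averaged over
  folds (mean of per-fold ratios, not ratios of pooled counts); the overall
  row is the unweighted macro-average over the four classes. Ratios with
  zero denominators are `NA`, never silently 0, and fold averages drop them.
* `multiclass_accuracy` (plain fraction correct, chance level 1/4) is
  reported alongside, because macro-averaged one-vs-rest ACC sits near 0.625
  for random 4-class predictions and is easily misread as signal.

PCA ordination (`pca_projection`) uses the wider ten-feature set and z-scored
features, dropping constants with a warning. `class_feature_tests` runs
Kruskal–Wallis across classes plus per-class Mann–Whitney U against the
pooled rest, reporting raw p-values with a significance flag at 0.001 and no
multiplicity correction — the comparisons are descriptive, not confirmatory.

## The synthetic generator

`generate_pattern()` emulates the four classes so the full pipeline can be
exercised without slide data:

* **T-cell area**: uniform placement in a disc, B fraction 0.17 (i.i.d.).
* **Mixed, unstructured**: uniform, B fraction 0.35, phenotypes independent
  of position.
* **Intermediately organized**: B fraction 0.60 with the B cells drawn from
  3 Gaussian clumps over a uniform T background.
* **TLO-like**: B fraction 0.60; the B cells fill a dense core disc that
  also contains 5% interspersed T cells, surrounded by a pure-T annulus.

The class B fractions follow the observed tendency of real infiltrates
(about 17 B cells per 100 in T-cell areas, rising to around 70 in organized
structures). The field radius is set so a uniform pattern of `n_cells`
(default 250) has mean nearest-neighbor spacing `mean_spacing_um` (default
8 µm — below the 11.385 µm cutoff, so intra-infiltrate edges survive the
default filter; the default region then covers roughly the area of a typical
annotated infiltrate). The TLO core is packed at 0.75× that spacing and its
mantle sized to hold the remaining T cells at the overall spacing. The only
noise model is optional Gaussian coordinate jitter.

What the generator does **not** emulate: detection noise (false or missed
cells, mistyped phenotypes), irregular infiltrate shapes, density gradients,
touching or nested infiltrates, and tissue architecture (vessels, tubuli,
tumor nests) that constrains real cell placement. Passing tests on synthetic
cohorts therefore demonstrates that the machinery measures what it claims to
measure on patterns with known structure — not that any particular accuracy
carries over to real slides, where ground truth must come from your own
annotations.

## Numerical choices and degenerate inputs

* Circumradius via `R = abc/4K`; a triangle counts as degenerate (infinite
  circumradius, never qualifying) when twice its area is below `1e-12` of
  the squared longest side. Strict inequality `R < t` throughout.
* Exact duplicate coordinates would break triangulation uniqueness; at load
  the record with the lexicographically smallest `cell_id` wins, with a
  warning.
* Fewer than 3 cells, or all cells collinear, is a degenerate point set:
  `build_delaunay()` signals it, `build_neighborhood_graphs()` degrades to
  an empty result with a warning.
* Point-in-polygon uses the even-odd rule, boundary-inclusive (a cell on the
  annotation outline is enclosed); self-intersecting annotation polygons are
  rejected by a pairwise proper-crossing test.
* Concave outlines are the boundary of the alpha complex at `alpha_px`
  (default: the graph's own `t`, keeping hull and graph consistent);
  boundary segments are those belonging to exactly one kept triangle, and
  when several rings arise the largest-area ring is returned.
* Cohort seeds are derived from a single master seed, so cohorts, folds and
  subsamples are reproducible end to end; identical configuration and seed
  produce byte-identical feature CSVs.

## Problem sizes in the test suite

The suite exercises brute-force oracles (triangle enumeration with
perpendicular-bisector circumcircles, flood-fill components, per-edge κ
counting) on 100+ random point sets of 10–45 cells, property checks
(monotonicity in `t`, label partition, κ monotone in `a`, planarity) on sets
up to 120 cells, and an end-to-end cohort of 50 patterns per class at 250
cells each for the cross-validated SVM, with a 20-repeat permutation null.
These sizes keep the full suite at a few minutes on one CPU while leaving
every code path covered; all of them scale with the parameters shown above
if you want heavier evidence.

## Known limitations

* Two phenotypes only; extending γ labels to more cell types requires a
  convention for the designated endpoint and is out of scope here.
* Infiltrate identity is purely graph-connectivity at one `t`; hierarchical
  or multi-scale decompositions are not attempted.
* κ does not separate early from mature TLOs — it is a "TLO-ness" marker,
  not a staging system, and coordinates alone cannot reveal the HEVs or FDCs
  that define mature TLOs.
* The density-map ROI proposer is a simple gridded counter meant for
  triaging large slides, not a detector in its own right.
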