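# lymphgraph

Graph-based detection and classification of lymphocytic infiltrates from
single-cell coordinates.

Pathologists assess inflammation in immunostained tissue sections — renal
allograft biopsies, tumor margins, chronically infected lung — largely by eye.
A recurring and difficult call is whether an accumulation of lymphocytes is a
nondescript infiltrate or an organized **tertiary lymphoid organ (TLO)**: an
ectopic lymphoid structure with a compact CD20⁺ B-cell core surrounded by a
CD3⁺ T-cell zone. `lymphgraph` provides a reproducible, observer-independent
alternative that works directly on detected cell centers (any upstream nucleus
detector that emits `x, y, phenotype` will do) and scales to whole slide
images.

## Method

Given the coordinates of all T and B cells in a region, the pipeline:

1. **Builds a Delaunay triangulation** over all cell centers, irrespective of
   phenotype.
2. **Filters edges by circumcircle radius**: every side of a triangle whose
   circumradius is smaller than a cutoff *t* becomes a graph edge (default
   *t* = 45 px at 0.253 µm/px, ≈ 11.4 µm — cell-contact distance). Each
   connected component of the resulting neighborhood graph *G* = (*V*, *E*)
   is one **infiltrate**.
3. **Labels edges** α (same phenotype) or γᵢ (inter-phenotype, where *i*
   counts the B–B edges at the edge's B endpoint) and computes per-infiltrate
   features: |V|, |V_B|/|V|, |E|, |E_α|, |E_α^B|/|E|, homogeneity
   H = |E_α|/|E|, the organization score

   κ(a) = ( |E| − |E_α| − Σ_{j≤a} |E_γⱼ| ) / ( |E| − |E_α| ),

   i.e. the fraction of T–B edges attached to a B cell with more than *a*
   B-cell neighbors — high exactly when B cells form compact zones bordered
   by T cells, and insensitive to single T cells dispersed inside a B core —
   plus the global clustering coefficient *C*, degree distribution *P(k)*,
   average degree ⟨K⟩ = 2|E|/|V|, and mean pairwise distance.
4. **Calibrates *t*** against pathologist-drawn infiltrate outlines: the
   smallest cutoff at which no annotated infiltrate falls apart into several
   components.
5. **Classifies** infiltrates into four organization classes — T-cell area,
   mixed unstructured, intermediately organized, TLO-like — with a
   radial-kernel SVM (features |E|, |E_α^B|/|E|, |V_B|/|V|, κ(2), κ(5)) under
   stratified 5-fold cross-validation, reporting per-class TPR/TNR/PPV/NPV/
   ACC/F1 and their macro-average, plus PCA ordination and Kruskal–Wallis /
   Mann–Whitney feature comparisons.

A synthetic point-pattern generator emulates the four classes at realistic
cell spacing, so the entire pipeline is testable without any slide data.

## Worked example

```r
library(lymphgraph)

# a simulated TLO-like region: dense B core, T mantle, 250 cells
cm <- generate_pattern(pattern_spec("TLO_LIKE", seed = 3))
cm
#> <cell_map> sim_tlo_like_s3: 250 cells (T=100, B=150), 0.253 um/px

infs <- build_neighborhood_graphs(cm)   # t = 45 px, min 10 cells
infs[[1]]
#> <infiltrate_graph> sim_tlo_like_s3_inf001: 224 nodes, 546 edges (t = 45 px, A = B)

features_table(infs)[, c("n_nodes", "frac_B", "homogeneity",
                         "kappa_2", "kappa_5", "avg_degree")]
#>   n_nodes    frac_B homogeneity kappa_2 kappa_5 avg_degree
#> 1     224 0.6696429   0.8534799  0.8625   0.075      4.875
```

The infiltrate retains 224 of the 250 cells (the sparse fringe falls below
the cutoff), two thirds of them B cells. κ(2) = 0.86 says that 86% of the
T–B interface edges touch a B cell embedded in a B cluster — the TLO
signature; a mixed, unstructured region with the same cell counts scores
κ(2) ≈ 0.1. The average degree (4.9) is typical for filtered planar Delaunay
graphs.

Classification end to end, on a balanced synthetic cohort:

```r
cohort <- generate_labeled_cohort(50, seed = 1)    # 200 patterns, 4 classes
feats  <- cohort_feature_table(cohort)
fm     <- assemble_feature_matrix(feats, feats$class_label)
cv     <- cross_validate_svm(fm$x, fm$y, k_folds = 5, seed = 1)
round(cv$overall, 3)
#>   TPR   TNR   PPV   NPV   ACC    F1
#> 0.975 0.992 0.977 0.992 0.988 0.975
```

A command-line front end with the subcommands `simulate`, `build-graphs`,
`features`, `calibrate`, `classify` and `hulls` is installed under
`inst/cli/lymphgraph.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/lymphgraph.R", package="lymphgraph"))')" \
    simulate --n-per-class 5 --seed 1 --out-dir sim/
```

## Documentation

The methods vignette (`vignettes/infiltrate-organization.Rmd`) describes the
model, parameter choices, the synthetic generator and its limits, and the
numerical conventions in detail.
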