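#' Feature table for a labelled cohort of cell maps
#'
#' Runs the graph-construction and feature steps over a whole cohort (e.g.
#' from [generate_labeled_cohort()]) and returns one feature row per
#' infiltrate, joined with the per-ROI class labels. With
#' `principal_only = TRUE` (the default) only the largest infiltrate of each
#' ROI is kept -- the synthetic generator emulates one infiltrate per region,
#' so the label refers to that structure.
#'
#' @param cohort list with `cell_maps` and `labels` as returned by
#'   [generate_labeled_cohort()], or a plain list of [cell_map()]s.
#' @param threshold_px,min_nodes,type_a passed to
#'   [build_neighborhood_graphs()].
#' @param kappa_orders passed to [features_table()].
#' @param principal_only keep only the largest infiltrate per ROI.
#' @return data.frame: [features_table()] columns plus `class_label` (when
#'   labels are available).
#' @export
cohort_feature_table <- function(cohort, threshold_px = NULL, min_nodes = 10,
                                 type_a = "B", kappa_orders = c(2, 5),
                                 principal_only = TRUE) {
  if (!is.null(cohort$cell_maps)) {
    cms <- cohort$cell_maps
    labels <- cohort$labels
  } else {
    cms <- cohort
    labels <- NULL
  }
  rows <- lapply(cms, function(cm) {
    infs <- build_neighborhood_graphs(cm, threshold_px = threshold_px,
                                      min_nodes = min_nodes, type_a = type_a)
    if (length(infs) == 0) return(NULL)
    if (principal_only) {
      infs <- infs[which.max(vapply(infs, function(g) nrow(g$cells), 0L))]
    }
    features_table(infs, kappa_orders)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(features_table(list(), kappa_orders))
  rownames(out) <- NULL
  if (!is.null(labels)) {
    out$class_label <- labels$class_label[match(out$roi_id, labels$roi_id)]
  }
  out
}
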