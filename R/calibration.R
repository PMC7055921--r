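#' Construct an annotation polygon
#'
#' Pathologist-drawn outline of one infiltrate, in the same pixel frame as the
#' cell table. The polygon must be simple (non-self-intersecting).
#'
#' @param vertices two-column matrix/data.frame of pixel coordinates (>= 3
#'   rows; a repeated closing vertex is dropped).
#' @param annotation_id,roi_id identifiers.
#' @param label optional organization class label.
#' @return Object of class `annotation_polygon`.
#' @export
annotation_polygon <- function(vertices, annotation_id = "ann", roi_id = "roi",
                               label = NULL) {
  v <- as.matrix(vertices)[, 1:2, drop = FALSE]
  storage.mode(v) <- "double"
  if (nrow(v) >= 4 && all(v[1, ] == v[nrow(v), ])) v <- v[-nrow(v), , drop = FALSE]
  if (nrow(v) < 3) lg_stop("bad annotation: fewer than 3 vertices", "lg_bad_annotation")
  if (!all(is.finite(v))) lg_stop("bad annotation: non-finite vertex", "lg_bad_annotation")
  if (!polygon_is_simple(v)) {
    lg_stop(sprintf("bad annotation: polygon %s is self-intersecting", annotation_id),
            "lg_bad_annotation")
  }
  structure(list(annotation_id = as.character(annotation_id),
                 roi_id = as.character(roi_id),
                 vertices = v, label = label),
            class = "annotation_polygon")
}

# proper-intersection test of segments (p1,p2) and (p3,p4), shared endpoints
# of adjacent polygon sides excluded by the caller
segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

polygon_is_simple <- function(v) {
  n <- nrow(v)
  idx <- cbind(seq_len(n), c(2:n, 1))
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next # adjacent around the wrap
      if (segments_cross(v[idx[i, 1], ], v[idx[i, 2], ],
                         v[idx[j, 1], ], v[idx[j, 2], ])) {
        return(FALSE)
      }
    }
  }
  TRUE
}

# even-odd point-in-polygon, boundary-inclusive; vectorized over points
point_in_polygon <- function(px, py, vx, vy, tol = 1e-9) {
  n <- length(vx)
  jx <- c(vx[-1], vx[1]); jy <- c(vy[-1], vy[1])
  scale <- max(abs(c(vx, vy)), 1)
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  for (s in seq_len(n)) {
    x1 <- vx[s]; y1 <- vy[s]; x2 <- jx[s]; y2 <- jy[s]
    # boundary test: collinear and within the segment's bounding box
    cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    on_seg <- abs(cross) <= tol * scale^2 &
      px >= pmin(x1, x2) - tol * scale & px <= pmax(x1, x2) + tol * scale &
      py >= pmin(y1, y2) - tol * scale & py <= pmax(y1, y2) + tol * scale
    on_edge <- on_edge | on_seg
    # even-odd ray cast toward +x
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
  }
  inside | on_edge
}

#' Cells enclosed by an annotation polygon
#'
#' Even-odd rule, boundary-inclusive: a cell exactly on the outline counts as
#' enclosed.
#'
#' @param cm a [cell_map()].
#' @param polygon an [annotation_polygon()].
#' @return Logical vector over `cm$cells` rows.
#' @export
cells_in_polygon <- function(cm, polygon) {
  stopifnot(inherits(cm, "cell_map"), inherits(polygon, "annotation_polygon"))
  point_in_polygon(cm$cells$x, cm$cells$y,
                   polygon$vertices[, 1], polygon$vertices[, 2])
}

#' Fragmentation of annotated infiltrates at a given threshold
#'
#' For each annotation, counts the connected components of the induced
#' subgraph of the `t`-filtered neighborhood graph restricted to the enclosed
#' cells. Edges to cells outside the annotation are ignored: connectivity is
#' scored inside the pathologist's outline only. Annotations enclosing fewer
#' than 2 cells are reported with `n_components = NA` ("empty") and excluded
#' from calibration scoring.
#'
#' @param cm a [cell_map()].
#' @param annotations list of [annotation_polygon()]s on this ROI.
#' @param threshold_px circumradius cutoff in pixels.
#' @param tri optional precomputed [build_delaunay()] table for `cm`.
#' @return data.frame with `annotation_id`, `n_cells`, `n_components`.
#' @export
fragmentation_at <- function(cm, annotations, threshold_px, tri = NULL) {
  stopifnot(inherits(cm, "cell_map"))
  tri <- tri %||% build_delaunay(cm)
  edges <- filtered_edges(tri, threshold_px)
  rows <- lapply(annotations, function(ann) {
    inside <- cells_in_polygon(cm, ann)
    nc <- sum(inside)
    if (nc < 2) {
      return(data.frame(annotation_id = ann$annotation_id, n_cells = nc,
                        n_components = NA_integer_))
    }
    members <- which(inside)
    sub <- edges[edges$from %in% members & edges$to %in% members, , drop = FALSE]
    idx <- integer(nrow(cm$cells)); idx[members] <- seq_along(members)
    ig <- igraph::make_empty_graph(length(members), directed = FALSE)
    if (nrow(sub) > 0) ig <- igraph::add_edges(ig, rbind(idx[sub$from], idx[sub$to]))
    data.frame(annotation_id = ann$annotation_id, n_cells = nc,
               n_components = igraph::components(ig)$no)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Calibrate the circumradius cutoff against pathologist annotations
#'
#' Sweeps a grid of candidate thresholds and, for each, measures the fraction
#' of annotated infiltrates whose enclosed cells form a single connected
#' component. The chosen cutoff is the smallest grid value whose fraction
#' reaches `target_fraction` (default 1: no annotated infiltrate may be
#' fragmented). If no grid value reaches the target, the value maximizing the
#' fraction is returned and flagged as a best approximation. The report also
#' gives the median length of kept versus removed Delaunay edges at the
#' chosen cutoff, in micrometers.
#'
#' @param cell_maps a [cell_map()] or list of them (matched to annotations by
#'   `roi_id`).
#' @param annotations list of [annotation_polygon()]s.
#' @param t_grid ascending candidate thresholds in pixels (default 5--100 by 5).
#' @param target_fraction required non-fragmentation fraction in `(0, 1]`.
#' @return Object of class `calibration_report`: list with `per_t`
#'   (data.frame `t_px`, `fraction_connected`, `n_scored`), `chosen_t`,
#'   `best_approximation` flag, `median_kept_edge_um`,
#'   `median_removed_edge_um` and `target_fraction`.
#' @export
calibrate_threshold <- function(cell_maps, annotations,
                                t_grid = seq(5, 100, by = 5),
                                target_fraction = 1.0) {
  if (inherits(cell_maps, "cell_map")) cell_maps <- list(cell_maps)
  stopifnot(length(t_grid) > 0, !is.unsorted(t_grid),
            target_fraction > 0, target_fraction <= 1)
  names(cell_maps) <- vapply(cell_maps, function(cm) cm$roi_id, "")
  tris <- lapply(cell_maps, build_delaunay)
  ann_by_roi <- split(annotations,
                      vapply(annotations, function(a) a$roi_id, ""))
  unknown <- setdiff(names(ann_by_roi), names(cell_maps))
  if (length(unknown) > 0) {
    lg_stop(sprintf("annotations reference unknown roi_id(s): %s",
                    paste(unknown, collapse = ", ")), "lg_bad_annotation")
  }
  per_t <- lapply(t_grid, function(t) {
    frag <- do.call(rbind, lapply(names(ann_by_roi), function(roi) {
      fragmentation_at(cell_maps[[roi]], ann_by_roi[[roi]], t, tri = tris[[roi]])
    }))
    scored <- frag[!is.na(frag$n_components), , drop = FALSE]
    data.frame(t_px = t, n_scored = nrow(scored),
               fraction_connected = if (nrow(scored) > 0)
                 mean(scored$n_components == 1) else NA_real_)
  })
  per_t <- do.call(rbind, per_t)
  if (all(is.na(per_t$fraction_connected)) || all(per_t$n_scored == 0)) {
    lg_stop("no ground truth: no annotation encloses >= 2 cells", "lg_no_ground_truth")
  }
  hit <- which(per_t$fraction_connected >= target_fraction)
  if (length(hit) > 0) {
    chosen <- per_t$t_px[hit[1]]
    approx <- FALSE
  } else {
    chosen <- per_t$t_px[which.max(per_t$fraction_connected)]
    approx <- TRUE
  }
  # kept vs removed Delaunay edge lengths at the chosen cutoff, pooled over ROIs
  kept_um <- removed_um <- numeric(0)
  for (roi in names(cell_maps)) {
    cm <- cell_maps[[roi]]
    e <- triangle_edges(tris[[roi]])
    len <- sqrt((cm$cells$x[e$from] - cm$cells$x[e$to])^2 +
                  (cm$cells$y[e$from] - cm$cells$y[e$to])^2) *
      cm$resolution_um_per_px
    is_kept <- e$min_circumradius_px < chosen
    kept_um <- c(kept_um, len[is_kept])
    removed_um <- c(removed_um, len[!is_kept])
  }
  structure(
    list(per_t = per_t, chosen_t = chosen, best_approximation = approx,
         target_fraction = target_fraction,
         median_kept_edge_um = stats::median(kept_um),
         median_removed_edge_um = if (length(removed_um) > 0)
           stats::median(removed_um) else NA_real_),
    class = "calibration_report"
  )
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf("<calibration_report> chosen t = %g px%s; kept/removed median edge %.2f / %.2f um\n",
              x$chosen_t,
              if (x$best_approximation) " (best approximation)" else "",
              x$median_kept_edge_um, x$median_removed_edge_um))
  invisible(x)
}
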