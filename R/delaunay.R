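#' Circumradius of a triangle
#'
#' Radius of the unique circle through three points, `R = abc / (4K)` with side
#' lengths `a`, `b`, `c` and triangle area `K`. Degenerate (collinear) triples
#' have no circumcircle and return `Inf`; degeneracy is declared when twice the
#' area falls below `1e-12` of the squared longest side.
#'
#' @param p1,p2,p3 numeric length-2 vectors, pixel coordinates.
#' @return Circumradius in the same units as the input, or `Inf`.
#' @examples
#' circumradius(c(0, 0), c(3, 0), c(0, 4)) # right triangle: hypotenuse/2 = 2.5
#' @export
circumradius <- function(p1, p2, p3) {
  circumradius_vec(p1[1], p1[2], p2[1], p2[2], p3[1], p3[2])
}

# vectorized workhorse over triangle vertex coordinates
circumradius_vec <- function(x1, y1, x2, y2, x3, y3) {
  a <- sqrt((x2 - x3)^2 + (y2 - y3)^2)
  b <- sqrt((x1 - x3)^2 + (y1 - y3)^2)
  ab <- sqrt((x1 - x2)^2 + (y1 - y2)^2)
  cross <- (x2 - x1) * (y3 - y1) - (y2 - y1) * (x3 - x1) # = 2 * area
  longest <- pmax(a, b, ab)
  r <- a * b * ab / (2 * abs(cross))
  r[abs(cross) < 1e-12 * longest^2] <- Inf
  r
}

#' Delaunay triangulation of a cell map
#'
#' Triangulates all cell coordinates irrespective of phenotype and annotates
#' each triangle with its circumcircle radius in pixels. This is the substrate
#' for the circumradius edge filter: a Delaunay side enters the neighborhood
#' graph when at least one of its incident triangles has circumradius below
#' the cutoff.
#'
#' @param cm a [cell_map()].
#' @return data.frame with integer vertex columns `i`, `j`, `k` (row indices
#'   into `cm$cells`) and `circumradius_px`.
#' @export
build_delaunay <- function(cm) {
  stopifnot(inherits(cm, "cell_map"))
  xy <- cm$cells
  if (nrow(xy) < 3) lg_stop("degenerate point set: fewer than 3 cells", "lg_degenerate")
  # collinearity: max |cross product| relative to squared extent
  dx <- xy$x - xy$x[1]; dy <- xy$y - xy$y[1]
  ref <- which.max(dx^2 + dy^2)
  cross <- dx[ref] * dy - dy[ref] * dx
  if (all(abs(cross) < 1e-12 * max(dx^2 + dy^2))) {
    lg_stop("degenerate point set: all cells collinear", "lg_degenerate")
  }
  dd <- tryCatch(
    deldir::deldir(xy$x, xy$y, suppressMsge = TRUE),
    error = function(e) lg_stop(paste0("degenerate point set: ", conditionMessage(e)),
                                "lg_degenerate")
  )
  tri <- deldir::triMat(dd)
  if (!is.null(tri) && is.null(dim(tri))) tri <- matrix(tri, nrow = 1)
  if (is.null(tri) || nrow(tri) == 0) {
    lg_stop("degenerate point set: no triangles", "lg_degenerate")
  }
  data.frame(
    i = tri[, 1], j = tri[, 2], k = tri[, 3],
    circumradius_px = circumradius_vec(
      xy$x[tri[, 1]], xy$y[tri[, 1]],
      xy$x[tri[, 2]], xy$y[tri[, 2]],
      xy$x[tri[, 3]], xy$y[tri[, 3]])
  )
}

# unique undirected edges (index pairs, from < to) from a triangle table,
# with the smallest circumradius over the triangles incident to each edge
triangle_edges <- function(tri) {
  from <- c(tri$i, tri$j, tri$i)
  to <- c(tri$j, tri$k, tri$k)
  r <- rep(tri$circumradius_px, 3)
  lo <- pmin(from, to); hi <- pmax(from, to)
  key <- paste(lo, hi, sep = "_")
  min_r <- tapply(r, key, min)
  first <- !duplicated(key)
  data.frame(
    from = lo[first], to = hi[first],
    min_circumradius_px = as.numeric(min_r[key[first]])
  )
}

# edge set surviving the circumradius filter at threshold t (strict <):
# an edge is kept iff ANY incident triangle has circumradius < t
filtered_edges <- function(tri, threshold_px) {
  e <- triangle_edges(tri)
  e[e$min_circumradius_px < threshold_px, c("from", "to"), drop = FALSE]
}

#' Construct a neighborhood graph from explicit nodes and edges
#'
#' Builds a labelled graph directly from a cell table and an edge list,
#' bypassing the Delaunay filter. Useful for worked examples and for
#' importing graphs built elsewhere; graphs produced by
#' [build_neighborhood_graphs()] additionally satisfy the Delaunay-subset
#' and planarity guarantees.
#'
#' @param cells data.frame with columns `cell_id`, `x`, `y`, `phenotype`.
#' @param edges two-column data.frame/matrix of node indices into `cells`
#'   (undirected; self-loops and duplicate edges are rejected).
#' @param roi_id,infiltrate_id identifiers.
#' @param threshold_px the cutoff associated with the graph (`Inf` if none).
#' @param type_a designated phenotype for edge labelling.
#' @param resolution_um_per_px scan resolution.
#' @return A labelled `neighborhood_graph`.
#' @export
neighborhood_graph <- function(cells, edges, roi_id = "roi",
                               threshold_px = Inf, type_a = "B",
                               resolution_um_per_px = 0.253,
                               infiltrate_id = NA_character_) {
  stopifnot(is.data.frame(cells),
            all(c("cell_id", "x", "y", "phenotype") %in% names(cells)))
  e <- as.data.frame(edges)[, 1:2]
  names(e) <- c("from", "to")
  n <- nrow(cells)
  if (nrow(e) > 0) {
    if (any(e$from < 1 | e$from > n | e$to < 1 | e$to > n)) {
      lg_stop("edge endpoint outside the cell table", "lg_bad_input")
    }
    if (any(e$from == e$to)) lg_stop("self-loops are not allowed", "lg_bad_input")
    key <- paste(pmin(e$from, e$to), pmax(e$from, e$to))
    if (anyDuplicated(key)) lg_stop("duplicate edges are not allowed", "lg_bad_input")
  }
  g <- new_neighborhood_graph(cells, e, roi_id = roi_id,
                              threshold_px = threshold_px, type_a = type_a,
                              resolution_um_per_px = resolution_um_per_px,
                              infiltrate_id = infiltrate_id)
  label_edges(g, type_a)
}

# internal constructor for a (possibly unlabeled) neighborhood graph
new_neighborhood_graph <- function(cells, edges, roi_id, threshold_px,
                                   type_a, resolution_um_per_px,
                                   infiltrate_id = NA_character_) {
  rownames(cells) <- NULL
  edges$length_px <- sqrt((cells$x[edges$from] - cells$x[edges$to])^2 +
                            (cells$y[edges$from] - cells$y[edges$to])^2)
  structure(
    list(roi_id = roi_id, infiltrate_id = infiltrate_id,
         cells = cells, edges = edges, threshold_px = threshold_px,
         type_a = type_a, resolution_um_per_px = resolution_um_per_px),
    class = "neighborhood_graph"
  )
}

#' Build circumradius-filtered neighborhood graphs (infiltrates)
#'
#' Computes the Delaunay triangulation of all cells, keeps the sides of every
#' triangle whose circumcircle radius is strictly smaller than `threshold_px`
#' (an edge survives if any of its incident triangles qualifies), and returns
#' each connected component with at least `min_nodes` cells as one infiltrate.
#' Edges are labelled by phenotype composition (see [label_edges()]).
#'
#' @param cm a [cell_map()].
#' @param threshold_px circumradius cutoff `t` in pixels. Default: 45 px at
#'   0.253 um/px, i.e. the same 11.385 um physical cutoff at any resolution.
#' @param min_nodes smallest component retained as an infiltrate (default 10).
#' @param type_a designated phenotype `A` for edge labelling (default `"B"`).
#' @return List of `neighborhood_graph` objects (class also
#'   `infiltrate_graph`), ordered by their smallest cell index. Attributes
#'   `n_components` and `n_discarded` record how many components were found
#'   and how many fell below `min_nodes`. A degenerate point set yields an
#'   empty list with a warning.
#' @export
build_neighborhood_graphs <- function(cm, threshold_px = NULL, min_nodes = 10,
                                      type_a = "B") {
  stopifnot(inherits(cm, "cell_map"))
  threshold_px <- threshold_px %||% default_threshold_px(cm$resolution_um_per_px)
  if (threshold_px < 0) lg_stop("threshold_px must be >= 0", "lg_bad_input")
  if (min_nodes < 1) lg_stop("min_nodes must be >= 1", "lg_bad_input")
  tri <- tryCatch(build_delaunay(cm), lg_degenerate = function(e) {
    warning(sprintf("%s: %s; no infiltrates", cm$roi_id, conditionMessage(e)),
            call. = FALSE)
    NULL
  })
  empty <- structure(list(), n_components = nrow(cm$cells),
                     n_discarded = nrow(cm$cells), threshold_px = threshold_px)
  if (is.null(tri)) return(empty)
  edges <- filtered_edges(tri, threshold_px)
  if (nrow(edges) == 0) return(empty)
  g <- igraph::graph_from_edgelist(as.matrix(edges), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nrow(cm$cells) - igraph::vcount(g)))
  comp <- igraph::components(g)
  sizes <- comp$csize
  keep <- which(sizes >= min_nodes)
  # deterministic order: by smallest member index
  first_idx <- vapply(keep, function(ci) min(which(comp$membership == ci)), 0L)
  keep <- keep[order(first_idx)]
  out <- vector("list", length(keep))
  for (s in seq_along(keep)) {
    ci <- keep[s]
    members <- which(comp$membership == ci)
    idx_map <- integer(nrow(cm$cells)); idx_map[members] <- seq_along(members)
    sub <- edges[edges$from %in% members & edges$to %in% members, , drop = FALSE]
    ng <- new_neighborhood_graph(
      cells = cm$cells[members, , drop = FALSE],
      edges = data.frame(from = idx_map[sub$from], to = idx_map[sub$to]),
      roi_id = cm$roi_id, threshold_px = threshold_px, type_a = type_a,
      resolution_um_per_px = cm$resolution_um_per_px,
      infiltrate_id = sprintf("%s_inf%03d", cm$roi_id, s))
    ng <- label_edges(ng, type_a)
    class(ng) <- c("infiltrate_graph", class(ng))
    out[[s]] <- ng
  }
  attr(out, "n_components") <- comp$no
  attr(out, "n_discarded") <- comp$no - length(keep)
  attr(out, "threshold_px") <- threshold_px
  out
}

#' @export
print.neighborhood_graph <- function(x, ...) {
  cat(sprintf("<%s> %s: %d nodes, %d edges (t = %.3g px, A = %s)\n",
              class(x)[1], x$infiltrate_id %||% x$roi_id,
              nrow(x$cells), nrow(x$edges), x$threshold_px, x$type_a))
  invisible(x)
}

#' Split an infiltrate into single-phenotype compartments
#'
#' Removes every inter-phenotype edge and returns the connected components of
#' what remains. Each compartment therefore contains cells of one phenotype
#' only; components of fewer than 3 cells (single cells and cell pairs) do not
#' span a compartment and are dropped.
#'
#' @param infiltrate a labelled `neighborhood_graph`.
#' @param min_cells smallest component that counts as a compartment (default 3).
#' @return List of compartments; each is a list with `phenotype`, `cells`
#'   (data.frame subset) and `indices` into the infiltrate's cell table.
#' @export
split_compartments <- function(infiltrate, min_cells = 3) {
  g <- ensure_labeled(infiltrate)
  alpha <- g$edges[g$edges$label == "alpha", , drop = FALSE]
  n <- nrow(g$cells)
  ig <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(alpha) > 0) {
    ig <- igraph::add_edges(ig, rbind(alpha$from, alpha$to))
  }
  comp <- igraph::components(ig)
  keep <- which(comp$csize >= min_cells)
  first_idx <- vapply(keep, function(ci) min(which(comp$membership == ci)), 0L)
  keep <- keep[order(first_idx)]
  lapply(keep, function(ci) {
    members <- which(comp$membership == ci)
    list(phenotype = g$cells$phenotype[members[1]],
         cells = g$cells[members, , drop = FALSE],
         indices = members)
  })
}

#' Concave (alpha-shape) outline of a point set
#'
#' Outline used to visualize infiltrates and compartments: the boundary of the
#' alpha complex, i.e. of the union of Delaunay triangles with circumradius
#' strictly below `alpha_px`. Matching `alpha_px` to the graph-construction
#' threshold `t` makes hull and graph mutually consistent. When several
#' boundary rings arise, the ring enclosing the largest area is returned.
#'
#' @param points two-column matrix or data.frame of pixel coordinates.
#' @param alpha_px circumradius cutoff for the alpha complex, in pixels.
#' @return A closed polygon as a two-column matrix (first vertex not
#'   repeated), or `NULL` when fewer than 3 points are given or no triangle
#'   qualifies.
#' @export
concave_hull <- function(points, alpha_px) {
  stopifnot(alpha_px > 0)
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  pts <- unique(pts)
  if (nrow(pts) < 3) return(NULL)
  cm <- tryCatch(
    cell_map(data.frame(cell_id = sprintf("p%d", seq_len(nrow(pts))),
                        x = pts[, 1], y = pts[, 2], phenotype = "T"),
             roi_id = "hull", resolution_um_per_px = 1),
    error = function(e) NULL)
  if (is.null(cm)) return(NULL)
  tri <- tryCatch(build_delaunay(cm), lg_degenerate = function(e) NULL)
  if (is.null(tri)) return(NULL)
  tri <- tri[tri$circumradius_px < alpha_px, , drop = FALSE]
  if (nrow(tri) == 0) return(NULL)
  # boundary edges belong to exactly one kept triangle
  from <- c(tri$i, tri$j, tri$i)
  to <- c(tri$j, tri$k, tri$k)
  lo <- pmin(from, to); hi <- pmax(from, to)
  key <- paste(lo, hi, sep = "_")
  once <- names(which(table(key) == 1))
  sel <- key %in% once & !duplicated(key)
  rings <- chain_rings(cbind(lo[sel], hi[sel]))
  if (length(rings) == 0) return(NULL)
  areas <- vapply(rings, function(r) abs(polygon_area(pts[r, 1], pts[r, 2])), 0)
  ring <- rings[[which.max(areas)]]
  pts[ring, , drop = FALSE]
}

# shoelace signed area of a closed polygon (first vertex not repeated)
polygon_area <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1)
  sum(x * y[j] - x[j] * y) / 2
}

# chain undirected boundary segments (2-column vertex-index matrix) into
# closed rings; at rare junction vertices an arbitrary unused segment is taken
chain_rings <- function(seg) {
  if (nrow(seg) == 0) return(list())
  adj <- split(c(seq_len(nrow(seg)), seq_len(nrow(seg))), c(seg[, 1], seg[, 2]))
  used <- logical(nrow(seg))
  rings <- list()
  for (start in seq_len(nrow(seg))) {
    if (used[start]) next
    ring <- seg[start, 1]
    cur <- seg[start, 2]
    used[start] <- TRUE
    repeat {
      ring <- c(ring, cur)
      nxt <- adj[[as.character(cur)]]
      nxt <- nxt[!used[nxt]]
      if (length(nxt) == 0) break
      e <- nxt[1]
      used[e] <- TRUE
      cur <- if (seg[e, 1] == cur) seg[e, 2] else seg[e, 1]
    }
    if (length(ring) >= 3 && ring[length(ring)] == ring[1]) {
      ring <- ring[-length(ring)]
    }
    if (length(ring) >= 3) rings[[length(rings) + 1]] <- ring
  }
  rings
}
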