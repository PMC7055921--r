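# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals: circumcircles
# are found by solving the perpendicular-bisector system, the Delaunay
# property is checked by point-in-circumcircle enumeration over all triples,
# and components come from a flood fill.

# circumcenter/radius of one triangle (rows of a 3x2 matrix)
oracle_circumcircle <- function(p) {
  ax <- p[1, 1]; ay <- p[1, 2]; bx <- p[2, 1]; by <- p[2, 2]
  cx <- p[3, 1]; cy <- p[3, 2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (abs(d) < 1e-12 * max(abs(c(ax, ay, bx, by, cx, cy, 1)))^2) {
    return(list(cx = NA, cy = NA, r = Inf))
  }
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
  list(cx = ux, cy = uy, r = sqrt((ux - ax)^2 + (uy - ay)^2))
}

# brute-force Delaunay triangulation: a triple is Delaunay iff no other point
# lies strictly inside its circumcircle; returns data.frame(i, j, k, r)
oracle_delaunay <- function(xy) {
  n <- nrow(xy)
  stopifnot(n >= 3)
  tri <- utils::combn(n, 3)
  x <- xy[, 1]; y <- xy[, 2]
  ax <- x[tri[1, ]]; ay <- y[tri[1, ]]
  bx <- x[tri[2, ]]; by <- y[tri[2, ]]
  cx <- x[tri[3, ]]; cy <- y[tri[3, ]]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
  r2 <- (ux - ax)^2 + (uy - ay)^2
  # squared distance of every point to every circumcenter (n x T)
  d2 <- outer(x, ux, function(p, c) (p - c)^2) +
    outer(y, uy, function(p, c) (p - c)^2)
  # own vertices sit on the circle; exclude them from the strict-inside test
  for (v in 1:3) d2[cbind(tri[v, ], seq_len(ncol(tri)))] <- Inf
  inside <- colSums(d2 < rep(r2, each = n) * (1 - 1e-9)) > 0
  keep <- which(!inside & abs(d) > 1e-12)
  data.frame(i = tri[1, keep], j = tri[2, keep], k = tri[3, keep],
             r = sqrt(r2[keep]))
}

edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "_")

# union of the sides of qualifying triangles (r < t), as a sorted integer
# edge matrix (global point indices)
oracle_filtered_edges <- function(tri, t) {
  q <- tri[tri$r < t, , drop = FALSE]
  a <- c(q$i, q$j, q$i); b <- c(q$j, q$k, q$k)
  keys <- unique(edge_key(a, b))
  if (length(keys) == 0) return(matrix(0L, 0, 2))
  em <- do.call(rbind, lapply(strsplit(keys, "_"), as.integer))
  em[order(em[, 1], em[, 2]), , drop = FALSE]
}

# edge keys in cell_id terms so graphs with re-indexed nodes are comparable
oracle_filtered_edge_keys <- function(tri, t, ids) {
  em <- oracle_filtered_edges(tri, t)
  if (nrow(em) == 0) return(character(0))
  sort(edge_key(ids[em[, 1]], ids[em[, 2]]))
}

graph_edge_keys <- function(g) {
  sort(edge_key(g$cells$cell_id[g$edges$from], g$cells$cell_id[g$edges$to]))
}

# flood-fill connected components over n nodes and a 2-column edge matrix
oracle_components <- function(n, edges) {
  comp <- rep(NA_integer_, n)
  adj <- vector("list", n)
  if (nrow(edges) > 0) {
    for (r in seq_len(nrow(edges))) {
      adj[[edges[r, 1]]] <- c(adj[[edges[r, 1]]], edges[r, 2])
      adj[[edges[r, 2]]] <- c(adj[[edges[r, 2]]], edges[r, 1])
    }
  }
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      queue <- c(queue, adj[[v]][is.na(comp[adj[[v]]])])
    }
  }
  comp
}

# kappa by direct per-edge enumeration: fraction of inter-type edges whose
# A endpoint has more than a A-neighbors
oracle_kappa <- function(g, a, type_a = g$type_a) {
  phen <- g$cells$phenotype
  e <- g$edges
  inter <- which(phen[e$from] != phen[e$to])
  if (length(inter) == 0) return(0)
  over <- vapply(inter, function(r) {
    a_end <- if (phen[e$from[r]] == type_a) e$from[r] else e$to[r]
    nb <- c(e$to[e$from == a_end], e$from[e$to == a_end])
    sum(phen[nb] == type_a) > a
  }, TRUE)
  mean(over)
}

# shoelace area of a closed polygon given as a two-column matrix
polygon_area_oracle <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  j <- c(2:length(x), 1)
  sum(x * y[j] - x[j] * y) / 2
}

# random generic-position point cloud in a box
random_points <- function(n, extent = 1000) {
  cbind(runif(n, 0, extent), runif(n, 0, extent))
}

random_cell_map <- function(n, extent = 1000, b_frac = 0.4, res = 1) {
  xy <- random_points(n, extent)
  cell_map(data.frame(cell_id = sprintf("c%03d", seq_len(n)),
                      x = xy[, 1], y = xy[, 2],
                      phenotype = ifelse(runif(n) < b_frac, "B", "T")),
           roi_id = "rand", resolution_um_per_px = res)
}

# regular grid cell map (spacing in px)
grid_cell_map <- function(nx, ny, spacing = 10, phenotype = "T", res = 1) {
  g <- expand.grid(x = (0:(nx - 1)) * spacing, y = (0:(ny - 1)) * spacing)
  cell_map(data.frame(cell_id = sprintf("g%04d", seq_len(nrow(g))),
                      x = g$x, y = g$y, phenotype = phenotype),
           roi_id = "grid", resolution_um_per_px = res)
}
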