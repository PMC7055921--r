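test_that("circumradius matches closed forms and handles degeneracy", {
  expect_equal(circumradius(c(0, 0), c(3, 0), c(0, 4)), 2.5)
  expect_equal(circumradius(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2)),
               1 / sqrt(3), tolerance = 1e-12)
  expect_identical(circumradius(c(0, 0), c(1, 0), c(2, 0)), Inf)
  # agrees with the perpendicular-bisector solver on random triangles
  set.seed(11)
  for (i in 1:50) {
    p <- matrix(runif(6, 0, 100), ncol = 2)
    expect_equal(circumradius(p[1, ], p[2, ], p[3, ]),
                 oracle_circumcircle(p)$r, tolerance = 1e-9)
  }
})

test_that("build_delaunay triangulates and rejects degenerate point sets", {
  cm3 <- cell_map(data.frame(cell_id = c("a", "b", "c"),
                             x = c(0, 3, 0), y = c(0, 0, 4), phenotype = "T"),
                  resolution_um_per_px = 1)
  tri <- build_delaunay(cm3)
  expect_equal(nrow(tri), 1)
  expect_equal(tri$circumradius_px, 2.5)

  sq <- grid_cell_map(2, 2, spacing = 10)
  tri <- build_delaunay(sq)
  expect_equal(nrow(tri), 2)
  expect_equal(tri$circumradius_px, rep(10 / sqrt(2), 2), tolerance = 1e-9)

  two <- cell_map(data.frame(cell_id = c("a", "b"), x = c(0, 1), y = c(0, 0),
                             phenotype = "T"), resolution_um_per_px = 1)
  expect_error(build_delaunay(two), "degenerate point set",
               class = "lg_degenerate")
  coll <- cell_map(data.frame(cell_id = letters[1:4], x = 1:4, y = 2 * (1:4),
                              phenotype = "T"), resolution_um_per_px = 1)
  expect_error(build_delaunay(coll), "degenerate point set",
               class = "lg_degenerate")
})

test_that("circumradius filter keeps the documented edge sets", {
  sq <- grid_cell_map(2, 2, spacing = 10)
  infs <- build_neighborhood_graphs(sq, threshold_px = 20, min_nodes = 2)
  expect_length(infs, 1)
  expect_equal(nrow(infs[[1]]$cells), 4)
  expect_equal(nrow(infs[[1]]$edges), 5) # 4 sides + 1 diagonal

  expect_length(build_neighborhood_graphs(sq, threshold_px = 0, min_nodes = 1), 0)

  # two clumps far apart stay separate infiltrates
  set.seed(7)
  clump <- function(cx, cy, tag) {
    data.frame(cell_id = sprintf("%s%02d", tag, 1:20),
               x = cx + runif(20, 0, 80), y = cy + runif(20, 0, 80),
               phenotype = "T")
  }
  cm <- cell_map(rbind(clump(0, 0, "a"), clump(600, 0, "b")),
                 resolution_um_per_px = 1)
  infs <- build_neighborhood_graphs(cm, threshold_px = 45, min_nodes = 2)
  expect_length(infs, 2)
})

test_that("degenerate input yields an empty result with a warning", {
  coll <- cell_map(data.frame(cell_id = letters[1:5], x = 1:5, y = rep(1, 5),
                              phenotype = "T"), resolution_um_per_px = 1)
  expect_warning(infs <- build_neighborhood_graphs(coll, threshold_px = 45),
                 "degenerate")
  expect_length(infs, 0)
})

test_that("filtered edges and components match brute-force oracles", {
  set.seed(101)
  for (rep in 1:25) {
    n <- sample(10:40, 1)
    cm <- random_cell_map(n, extent = 300)
    tri_oracle <- oracle_delaunay(cbind(cm$cells$x, cm$cells$y))
    tri_pkg <- build_delaunay(cm)
    tri_key <- function(i, j, k) {
      apply(cbind(i, j, k), 1, function(v) paste(sort(v), collapse = "_"))
    }
    expect_equal(sort(tri_key(tri_pkg$i, tri_pkg$j, tri_pkg$k)),
                 sort(tri_key(tri_oracle$i, tri_oracle$j, tri_oracle$k)))
    t <- runif(1, 10, 120)
    infs <- build_neighborhood_graphs(cm, threshold_px = t, min_nodes = 1)
    got <- sort(as.character(unlist(lapply(infs, graph_edge_keys))))
    expect_equal(got, oracle_filtered_edge_keys(tri_oracle, t, cm$cells$cell_id))
    # component sizes agree with a flood fill over the oracle edge set
    em <- oracle_filtered_edges(tri_oracle, t)
    if (nrow(em) == 0) {
      expect_length(infs, 0)
    } else {
      comp <- oracle_components(n, em)
      expect_equal(sort(vapply(infs, function(g) nrow(g$cells), 0L)),
                   sort(as.integer(table(comp))))
    }
  }
})

test_that("edge sets grow monotonically in t with correct limits", {
  set.seed(55)
  for (rep in 1:10) {
    cm <- random_cell_map(sample(20:80, 1), extent = 500)
    ts <- sort(runif(3, 5, 400))
    keys <- lapply(ts, function(t) {
      sort(unlist(lapply(build_neighborhood_graphs(cm, t, min_nodes = 1),
                         graph_edge_keys)))
    })
    expect_true(all(keys[[1]] %in% keys[[2]]))
    expect_true(all(keys[[2]] %in% keys[[3]]))
    # t -> Inf recovers the full (connected) Delaunay graph
    full <- build_neighborhood_graphs(cm, Inf, min_nodes = 1)
    expect_length(full, 1)
    tri <- build_delaunay(cm)
    expect_equal(graph_edge_keys(full[[1]]),
                 oracle_filtered_edge_keys(
                   data.frame(i = tri$i, j = tri$j, k = tri$k,
                              r = tri$circumradius_px), Inf,
                   cm$cells$cell_id))
    # planarity bound on every output graph
    for (g in full) {
      expect_lte(nrow(g$edges), 3 * nrow(g$cells) - 6)
    }
  }
})

test_that("min_nodes filters small components and is reported", {
  set.seed(3)
  clump <- function(cx, n, tag) {
    data.frame(cell_id = sprintf("%s%02d", tag, seq_len(n)),
               x = cx + runif(n, 0, 60), y = runif(n, 0, 60), phenotype = "T")
  }
  cm <- cell_map(rbind(clump(0, 20, "a"), clump(800, 4, "b")),
                 resolution_um_per_px = 1)
  infs <- build_neighborhood_graphs(cm, threshold_px = 45, min_nodes = 10)
  expect_length(infs, 1)
  expect_gte(attr(infs, "n_discarded"), 1)
})

test_that("split_compartments keeps same-phenotype components of >= 3 cells", {
  tri_cells <- data.frame(cell_id = c("a", "b", "c"), x = c(0, 10, 5),
                          y = c(0, 0, 8), phenotype = "T")
  g <- neighborhood_graph(tri_cells, cbind(c(1, 2, 1), c(2, 3, 3)))
  comps <- split_compartments(g)
  expect_length(comps, 1)
  expect_equal(nrow(comps[[1]]$cells), 3)
  expect_equal(comps[[1]]$phenotype, "T")

  # star: B center, 4 T leaves, all edges inter-type -> no compartment
  star <- data.frame(cell_id = sprintf("s%d", 1:5),
                     x = c(0, 1, -1, 0, 0), y = c(0, 0, 0, 1, -1),
                     phenotype = c("B", "T", "T", "T", "T"))
  g <- neighborhood_graph(star, cbind(1, 2:5))
  expect_length(split_compartments(g), 0)
})

test_that("a TLO-like pattern yields one dominant B compartment", {
  cm <- generate_pattern(pattern_spec("TLO_LIKE", seed = 42))
  infs <- build_neighborhood_graphs(cm)
  main <- infs[[which.max(vapply(infs, function(g) nrow(g$cells), 0L))]]
  comps <- split_compartments(main)
  b_comps <- Filter(function(cp) cp$phenotype == "B", comps)
  expect_gte(length(b_comps), 1)
  n_b_in_graph <- sum(main$cells$phenotype == "B")
  biggest <- max(vapply(b_comps, function(cp) nrow(cp$cells), 0L))
  expect_gte(biggest / n_b_in_graph, 0.9)
})

test_that("concave hull outlines points at the alpha-complex boundary", {
  expect_null(concave_hull(cbind(c(0, 1), c(0, 0)), alpha_px = 10))
  tri <- concave_hull(cbind(c(0, 10, 0), c(0, 0, 10)), alpha_px = 50)
  expect_equal(nrow(tri), 3)
  expect_equal(abs(polygon_area_oracle(tri)), 50)
  grid <- expand.grid(x = (0:10) * 10, y = (0:10) * 10)
  hull <- concave_hull(as.matrix(grid), alpha_px = 20)
  area <- abs(polygon_area_oracle(hull))
  expect_lt(abs(area - 10000) / 10000, 0.05)
})
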