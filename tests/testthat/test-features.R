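make_graph <- function(phen, edges, res = 1) {
  n <- length(phen)
  cells <- data.frame(cell_id = sprintf("c%02d", seq_len(n)),
                      x = seq_len(n) * 10, y = (seq_len(n) %% 2) * 7,
                      phenotype = phen)
  neighborhood_graph(cells, edges, resolution_um_per_px = res)
}

test_that("label_edges assigns alpha and gamma labels per definition", {
  g <- make_graph(c("T", "T", "T"), cbind(c(1, 2, 1), c(2, 3, 3)))
  s <- edge_label_summary(g)
  expect_equal(s$n_edges, 3)
  expect_equal(s$n_alpha, 3)
  expect_length(s$gamma_counts, 0)

  # one B joined to 3 T leaves: B endpoint has zero B-B edges -> all gamma_0
  g <- make_graph(c("B", "T", "T", "T"), cbind(1, 2:4))
  s <- edge_label_summary(g)
  expect_equal(unname(s$gamma_counts["0"]), 3L)
  expect_equal(s$n_alpha, 0)

  # B1-B2 alpha edge plus one T leaf on each B -> both inter edges gamma_1
  g <- make_graph(c("B", "B", "T", "T"), cbind(c(1, 1, 2), c(2, 3, 4)))
  s <- edge_label_summary(g)
  expect_equal(s$gamma_counts, c("1" = 2L))

  # graphs with more than two phenotypes are rejected at labelling time
  expect_error(make_graph(c("B", "T", "X"), cbind(c(1, 2), c(2, 3))),
               "multi-type", class = "lg_multi_type")
})

test_that("label partition identity holds on random graphs", {
  set.seed(21)
  for (rep in 1:20) {
    cm <- random_cell_map(sample(20:100, 1), extent = 400)
    infs <- build_neighborhood_graphs(cm, runif(1, 20, 80), min_nodes = 1)
    for (g in infs) {
      s <- edge_label_summary(g)
      expect_equal(s$n_alpha + sum(s$gamma_counts), s$n_edges)
      expect_lte(s$n_alpha_a, s$n_alpha)
    }
  }
})

test_that("kappa matches its definition and conventions", {
  # gamma_counts {1: 2}: kappa(0) = 1, kappa(1) = 0
  g <- make_graph(c("B", "B", "T", "T"), cbind(c(1, 1, 2), c(2, 3, 4)))
  expect_equal(unname(kappa_score(g, 0:1)), c(1, 0))

  # no inter-type edges -> 0 by convention, flagged
  g <- make_graph(c("T", "T", "T"), cbind(c(1, 2), c(2, 3)))
  k <- kappa_score(g, c(0, 2, 5))
  expect_equal(as.numeric(k), c(0, 0, 0))
  expect_true(attr(k, "degenerate"))
})

test_that("kappa is non-increasing in a and matches brute enumeration", {
  set.seed(33)
  for (rep in 1:20) {
    cm <- random_cell_map(sample(30:150, 1), extent = 600)
    infs <- build_neighborhood_graphs(cm, runif(1, 30, 90), min_nodes = 3)
    for (g in infs) {
      ks <- unname(kappa_score(g, 0:8))
      expect_true(all(diff(ks) <= 1e-12))
      s <- edge_label_summary(g)
      max_idx <- if (length(s$gamma_counts) > 0)
        max(as.integer(names(s$gamma_counts))) else 0
      expect_equal(as.numeric(kappa_score(g, max_idx)), 0)
      for (a in c(0, 2, 5)) {
        expect_equal(as.numeric(kappa_score(g, a)), oracle_kappa(g, a))
      }
    }
  }
})

test_that("relabelling the designated type changes only type-aware features", {
  set.seed(9)
  cm <- random_cell_map(80, extent = 400)
  g_b <- build_neighborhood_graphs(cm, 60, min_nodes = 5, type_a = "B")[[1]]
  g_t <- label_edges(g_b, "T")
  sb <- edge_label_summary(g_b); st <- edge_label_summary(g_t)
  expect_equal(sb$n_alpha, st$n_alpha)
  expect_equal(homogeneity(sb), homogeneity(st))
  expect_equal(clustering_coefficient(g_b), clustering_coefficient(g_t))
  expect_equal(degree_statistics(g_b), degree_statistics(g_t))
  fb <- compute_feature_vector(g_b); ft <- compute_feature_vector(g_t)
  expect_equal(fb$frac_A + ft$frac_A, 1)
})

test_that("homogeneity is the alpha-edge fraction", {
  g <- make_graph(c("T", "T", "B"), cbind(c(1, 2, 1), c(2, 3, 3)))
  expect_equal(homogeneity(g), 1 / 3)
  expect_equal(homogeneity(make_graph(c("T", "T"), cbind(1, 2))), 1)
  expect_equal(homogeneity(make_graph(c("T", "B"), cbind(1, 2))), 0)
  edgeless <- make_graph(c("T", "B"), matrix(0, 0, 2))
  expect_error(homogeneity(edgeless), "edgeless", class = "lg_edgeless")
})

test_that("clustering coefficient follows the averaged-local convention", {
  expect_equal(clustering_coefficient(
    make_graph(rep("T", 3), cbind(c(1, 2, 1), c(2, 3, 3)))), 1)
  expect_equal(clustering_coefficient(
    make_graph(rep("T", 3), cbind(c(1, 2), c(2, 3)))), 0)
  # square with one diagonal: locals (2/3, 1, 2/3, 1) -> 5/6
  g <- make_graph(rep("T", 4), cbind(c(1, 2, 3, 4, 1), c(2, 3, 4, 1, 3)))
  expect_equal(clustering_coefficient(g), 5 / 6)
})

test_that("clustering coefficient agrees with igraph on random graphs", {
  set.seed(14)
  for (rep in 1:15) {
    cm <- random_cell_map(sample(20:120, 1), extent = 500)
    infs <- build_neighborhood_graphs(cm, runif(1, 30, 100), min_nodes = 1)
    for (g in infs) {
      ig <- igraph::make_empty_graph(nrow(g$cells), directed = FALSE)
      if (nrow(g$edges) > 0) {
        ig <- igraph::add_edges(ig, rbind(g$edges$from, g$edges$to))
      }
      expect_equal(clustering_coefficient(g),
                   igraph::transitivity(ig, type = "localaverage",
                                        isolates = "zero"),
                   tolerance = 1e-12)
    }
  }
})

test_that("degree statistics normalize correctly", {
  g <- make_graph(rep("T", 3), cbind(c(1, 2, 1), c(2, 3, 3)))
  ds <- degree_statistics(g)
  expect_equal(ds$P_k, c("2" = 1))
  expect_equal(ds$avg_degree, 2)
  g <- make_graph(rep("T", 2), cbind(1, 2))
  expect_equal(degree_statistics(g)$avg_degree, 1)
  g <- make_graph(rep("T", 4), cbind(c(1, 2, 3, 4, 1), c(2, 3, 4, 1, 3)))
  ds <- degree_statistics(g)
  expect_equal(ds$avg_degree, 2.5)
  expect_equal(ds$P_k, c("2" = 0.5, "3" = 0.5))
  set.seed(4)
  cm <- random_cell_map(60, extent = 300)
  for (g in build_neighborhood_graphs(cm, 40, min_nodes = 1)) {
    ds <- degree_statistics(g)
    expect_equal(sum(ds$P_k), 1)
    expect_equal(sum(as.integer(names(ds$P_k)) * ds$P_k), ds$avg_degree)
  }
})

test_that("mean pairwise distance reports micrometers", {
  two <- neighborhood_graph(
    data.frame(cell_id = c("a", "b"), x = c(0, 100), y = c(0, 0),
               phenotype = "T"),
    cbind(1, 2), resolution_um_per_px = 0.253)
  expect_equal(as.numeric(mean_pairwise_distance(two)), 25.3)
  sq <- make_graph(rep("T", 4), cbind(c(1, 2, 3, 4), c(2, 3, 4, 1)))
  sq$cells$x <- c(0, 10, 10, 0); sq$cells$y <- c(0, 0, 10, 10)
  expect_equal(as.numeric(mean_pairwise_distance(sq)),
               (4 * 10 + 2 * 10 * sqrt(2)) / 6)
  # seeded subsample above the cap approximates the exact mean
  set.seed(2)
  cm <- random_cell_map(400, extent = 2000)
  g <- build_neighborhood_graphs(cm, Inf, min_nodes = 1)[[1]]
  exact <- mean_pairwise_distance(g)
  sub <- mean_pairwise_distance(g, exact_cap = 100, n_sample = 2e5)
  expect_true(isTRUE(attr(sub, "subsampled")))
  expect_equal(as.numeric(sub), as.numeric(exact), tolerance = 0.02)
  one <- make_graph("T", matrix(0, 0, 2))
  expect_error(mean_pairwise_distance(one), "undefined", class = "lg_bad_input")
})

test_that("feature vectors satisfy their internal invariants", {
  g <- make_graph(rep("T", 3), cbind(c(1, 2, 1), c(2, 3, 3)))
  fv <- compute_feature_vector(g)
  expect_equal(fv$frac_A, 0)
  expect_equal(fv$homogeneity, 1)
  expect_equal(as.numeric(fv$kappa), c(0, 0))

  cm <- generate_pattern(pattern_spec("TLO_LIKE", seed = 7))
  infs <- build_neighborhood_graphs(cm)
  for (g in infs) {
    fv <- compute_feature_vector(g)
    expect_gte(fv$homogeneity, 0); expect_lte(fv$homogeneity, 1)
    expect_true(all(fv$kappa >= 0 & fv$kappa <= 1))
    expect_gte(fv$clustering_C, 0); expect_lte(fv$clustering_C, 1)
    expect_equal(sum(fv$degree_distribution), 1)
    expect_equal(fv$avg_degree, 2 * fv$n_edges / fv$n_nodes)
    expect_gte(fv$frac_A, 0); expect_lte(fv$frac_A, 1)
  }
})

test_that("features_table emits the documented schema", {
  cm <- generate_pattern(pattern_spec("INTERMEDIATE", seed = 5))
  infs <- build_neighborhood_graphs(cm)
  tab <- features_table(infs)
  expect_named(tab, c("roi_id", "infiltrate_id", "n_nodes", "frac_B",
                      "n_edges", "n_alpha", "frac_alpha_B", "homogeneity",
                      "kappa_2", "kappa_5", "clustering_C", "avg_degree",
                      "mean_pairwise_dist_um"))
  expect_equal(nrow(tab), length(infs))
  empty <- features_table(list())
  expect_equal(nrow(empty), 0)
  expect_named(empty, names(tab))
  dt <- degree_table(infs)
  expect_named(dt, c("infiltrate_id", "k", "P_k"))
  for (id in unique(dt$infiltrate_id)) {
    expect_equal(sum(dt$P_k[dt$infiltrate_id == id]), 1)
  }
})
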