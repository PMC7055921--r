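#' Label graph edges by phenotype composition
#'
#' An edge is labelled `alpha` when both endpoints share the same phenotype.
#' Every remaining (inter-phenotype) edge is labelled `gamma_i`, where `i` is
#' the number of A--A alpha edges incident to the edge's endpoint of the
#' designated phenotype `A`. With exactly two phenotypes every inter-type edge
#' has exactly one A endpoint, so the label is well defined. High gamma
#' indices mark interfaces where the A side is itself densely A-connected --
#' the signature of a compact B-cell zone bordered by T cells when `A = "B"`.
#'
#' @param graph a `neighborhood_graph`.
#' @param type_a designated phenotype `A` (defaults to the graph's `type_a`).
#' @return The graph with per-edge columns `label` (`"alpha"`/`"gamma"`) and
#'   `gamma_index` (integer, `NA` for alpha edges) filled in.
#' @export
label_edges <- function(graph, type_a = graph$type_a) {
  stopifnot(inherits(graph, "neighborhood_graph"))
  phen <- graph$cells$phenotype
  if (length(unique(phen)) > 2) {
    lg_stop("multi-type not supported: more than two phenotypes present",
            "lg_multi_type")
  }
  e <- graph$edges
  is_a_cell <- phen == type_a
  same <- phen[e$from] == phen[e$to]
  # A-A degree of each node, counted over alpha edges between A cells
  aa <- same & is_a_cell[e$from]
  aa_deg <- tabulate(c(e$from[aa], e$to[aa]), nbins = nrow(graph$cells))
  a_end <- ifelse(is_a_cell[e$from], e$from, e$to)
  e$label <- ifelse(same, "alpha", "gamma")
  e$gamma_index <- ifelse(same, NA_integer_, aa_deg[a_end])
  graph$edges <- e
  graph$type_a <- type_a
  graph
}

ensure_labeled <- function(graph) {
  if (is.null(graph$edges$label)) label_edges(graph) else graph
}

#' Summarize edge labels of a neighborhood graph
#'
#' @param graph a labelled `neighborhood_graph` (labelled on the fly if not).
#' @return Object of class `edge_label_summary`: list with `n_edges`,
#'   `n_alpha`, `n_alpha_a` (alpha edges between two A cells) and
#'   `gamma_counts`, a named integer vector mapping gamma index `i` to the
#'   number of inter-type edges with that index. The counts partition the edge
#'   set: `n_alpha + sum(gamma_counts) == n_edges`.
#' @export
edge_label_summary <- function(graph) {
  g <- ensure_labeled(graph)
  e <- g$edges
  is_a <- g$cells$phenotype == g$type_a
  alpha <- e$label == "alpha"
  gi <- e$gamma_index[!alpha]
  gamma_counts <- integer(0)
  if (length(gi) > 0) {
    tab <- table(gi)
    gamma_counts <- as.integer(tab)
    names(gamma_counts) <- names(tab)
  }
  structure(
    list(n_edges = nrow(e),
         n_alpha = sum(alpha),
         n_alpha_a = sum(alpha & is_a[e$from]),
         gamma_counts = gamma_counts),
    class = "edge_label_summary"
  )
}

#' TLO-like organization score kappa(a)
#'
#' `kappa(a) = (|E| - |Ealpha| - sum_{j<=a} |Egamma_j|) / (|E| - |Ealpha|)`:
#' the fraction of inter-phenotype edges whose gamma index exceeds `a`, i.e.
#' whose A endpoint has more than `a` A--A neighbors. The score is high when
#' A cells (B cells by default) form compact zones bordered by the other
#' phenotype, as in tertiary lymphoid organs, and is robust to single T cells
#' dispersed inside a B-cell core. A graph without inter-type edges has no
#' TLO interface; by convention its kappa is 0 (flagged via the `"degenerate"`
#' attribute).
#'
#' @param x an `edge_label_summary` or a labelled `neighborhood_graph`.
#' @param a non-negative integer order(s); may be a vector.
#' @return Numeric vector of values in `[0, 1]`, one per element of `a`.
#' @export
kappa_score <- function(x, a = c(2, 5)) {
  if (inherits(x, "neighborhood_graph")) x <- edge_label_summary(x)
  stopifnot(inherits(x, "edge_label_summary"), all(a >= 0))
  denom <- x$n_edges - x$n_alpha
  if (denom == 0) {
    out <- rep(0, length(a))
    names(out) <- a
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  idx <- as.integer(names(x$gamma_counts))
  out <- vapply(a, function(ai) sum(x$gamma_counts[idx > ai]) / denom, 0)
  names(out) <- a
  out
}

#' Homogeneity of a neighborhood graph
#'
#' Fraction of edges joining cells of the same phenotype,
#' `H = |Ealpha| / |E|`.
#'
#' @inheritParams kappa_score
#' @return Value in `[0, 1]`.
#' @export
homogeneity <- function(x) {
  if (inherits(x, "neighborhood_graph")) x <- edge_label_summary(x)
  stopifnot(inherits(x, "edge_label_summary"))
  if (x$n_edges == 0) lg_stop("edgeless graph: homogeneity undefined", "lg_edgeless")
  x$n_alpha / x$n_edges
}

#' Global clustering coefficient
#'
#' Average of the local clustering coefficients over all nodes,
#' `C = (1/|V|) * sum_l 2 n_l / (|N_l| (|N_l| - 1))`, where `n_l` counts edges
#' among the neighbors `N_l` of node `l`. Nodes with fewer than two neighbors
#' contribute 0 but remain in the `1/|V|` prefactor.
#'
#' @param graph a `neighborhood_graph`.
#' @return Value in `[0, 1]`.
#' @export
clustering_coefficient <- function(graph) {
  stopifnot(inherits(graph, "neighborhood_graph"))
  n <- nrow(graph$cells)
  stopifnot(n >= 1)
  e <- graph$edges
  adj <- vector("list", n)
  for (r in seq_len(nrow(e))) {
    adj[[e$from[r]]] <- c(adj[[e$from[r]]], e$to[r])
    adj[[e$to[r]]] <- c(adj[[e$to[r]]], e$from[r])
  }
  local <- vapply(seq_len(n), function(l) {
    nb <- adj[[l]]
    k <- length(nb)
    if (k < 2) return(0)
    m <- sum(vapply(nb, function(v) sum(adj[[v]] %in% nb), 0)) / 2
    2 * m / (k * (k - 1))
  }, 0)
  mean(local)
}

#' Degree distribution and average degree
#'
#' @param graph a `neighborhood_graph`.
#' @return List with `P_k`, a named numeric vector `P(k) = n_k / |V|` over the
#'   observed degrees (summing to 1), and `avg_degree = 2|E|/|V|`.
#' @export
degree_statistics <- function(graph) {
  stopifnot(inherits(graph, "neighborhood_graph"))
  n <- nrow(graph$cells)
  stopifnot(n >= 1)
  deg <- tabulate(c(graph$edges$from, graph$edges$to), nbins = n)
  tab <- table(deg)
  p_k <- as.numeric(tab) / n
  names(p_k) <- names(tab)
  list(P_k = p_k, avg_degree = 2 * nrow(graph$edges) / n)
}

#' Mean pairwise Euclidean distance between nodes, in micrometers
#'
#' Exact mean over all unordered node pairs up to `exact_cap` nodes; above
#' that a seeded random sample of `n_sample` pairs estimates the mean (the
#' result then carries attribute `subsampled = TRUE`).
#'
#' @param graph a `neighborhood_graph`.
#' @param resolution_um_per_px resolution; defaults to the graph's.
#' @param exact_cap largest node count for the exact all-pairs mean.
#' @param n_sample number of sampled pairs above the cap.
#' @param sample_seed seed for the pair subsample.
#' @return Mean distance in micrometers.
#' @export
mean_pairwise_distance <- function(graph,
                                   resolution_um_per_px = graph$resolution_um_per_px,
                                   exact_cap = 5000, n_sample = 1e6,
                                   sample_seed = 1) {
  stopifnot(inherits(graph, "neighborhood_graph"))
  n <- nrow(graph$cells)
  if (n < 2) lg_stop("mean pairwise distance undefined for < 2 nodes", "lg_bad_input")
  x <- graph$cells$x; y <- graph$cells$y
  if (n <= exact_cap) {
    return(mean(stats::dist(cbind(x, y))) * resolution_um_per_px)
  }
  d <- with_seed(sample_seed, {
    i <- sample.int(n, n_sample, replace = TRUE)
    j <- sample.int(n - 1, n_sample, replace = TRUE)
    j <- ifelse(j >= i, j + 1L, j) # uniform over off-diagonal pairs
    mean(sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2))
  })
  structure(d * resolution_um_per_px, subsampled = TRUE)
}

#' Full feature vector of one infiltrate
#'
#' Assembles the per-infiltrate feature suite: node and edge counts, fraction
#' of designated-type cells, fraction of A--A edges, homogeneity, the
#' organization scores `kappa(a)`, global clustering coefficient, degree
#' distribution, average degree, and mean pairwise distance.
#'
#' @param infiltrate a labelled `neighborhood_graph`.
#' @param kappa_orders integer orders at which to evaluate kappa
#'   (default `c(2, 5)`, the orders used for classification).
#' @return Object of class `feature_vector` (a list).
#' @export
compute_feature_vector <- function(infiltrate, kappa_orders = c(2, 5)) {
  g <- ensure_labeled(infiltrate)
  s <- edge_label_summary(g)
  n <- nrow(g$cells)
  deg <- degree_statistics(g)
  structure(
    list(
      roi_id = g$roi_id,
      infiltrate_id = g$infiltrate_id,
      n_nodes = n,
      frac_A = mean(g$cells$phenotype == g$type_a),
      n_edges = s$n_edges,
      n_alpha = s$n_alpha,
      frac_alpha_A = if (s$n_edges > 0) s$n_alpha_a / s$n_edges else NA_real_,
      homogeneity = if (s$n_edges > 0) homogeneity(s) else NA_real_,
      kappa = kappa_score(s, kappa_orders),
      clustering_C = clustering_coefficient(g),
      degree_distribution = deg$P_k,
      avg_degree = deg$avg_degree,
      mean_pairwise_dist_um = if (n >= 2) as.numeric(mean_pairwise_distance(g)) else NA_real_,
      type_a = g$type_a
    ),
    class = "feature_vector"
  )
}

#' Feature table for a collection of infiltrates
#'
#' One row per infiltrate with the flat features; the degree distribution is
#' available separately via [degree_table()]. Column names follow the default
#' designation `A = B` (`frac_B`, `frac_alpha_B`).
#'
#' @param infiltrates list of labelled `neighborhood_graph` objects.
#' @param kappa_orders orders for the kappa columns (named `kappa_<a>`).
#' @return data.frame with columns `roi_id, infiltrate_id, n_nodes, frac_B,
#'   n_edges, n_alpha, frac_alpha_B, homogeneity, kappa_2, kappa_5,
#'   clustering_C, avg_degree, mean_pairwise_dist_um` (kappa columns per
#'   `kappa_orders`).
#' @export
features_table <- function(infiltrates, kappa_orders = c(2, 5)) {
  kcols <- paste0("kappa_", kappa_orders)
  cols <- c("roi_id", "infiltrate_id", "n_nodes", "frac_B", "n_edges",
            "n_alpha", "frac_alpha_B", "homogeneity", kcols,
            "clustering_C", "avg_degree", "mean_pairwise_dist_um")
  if (length(infiltrates) == 0) {
    out <- c(list(roi_id = character(0), infiltrate_id = character(0),
                  n_nodes = integer(0)),
             stats::setNames(rep(list(numeric(0)), length(cols) - 3),
                             cols[-(1:3)]))
    return(as.data.frame(out))
  }
  rows <- lapply(infiltrates, function(g) {
    fv <- compute_feature_vector(g, kappa_orders)
    row <- data.frame(roi_id = fv$roi_id, infiltrate_id = fv$infiltrate_id,
                      n_nodes = fv$n_nodes, frac_B = fv$frac_A,
                      n_edges = fv$n_edges, n_alpha = fv$n_alpha,
                      frac_alpha_B = fv$frac_alpha_A,
                      homogeneity = fv$homogeneity,
                      stringsAsFactors = FALSE)
    for (i in seq_along(kappa_orders)) row[[kcols[i]]] <- unname(fv$kappa[i])
    row$clustering_C <- fv$clustering_C
    row$avg_degree <- fv$avg_degree
    row$mean_pairwise_dist_um <- fv$mean_pairwise_dist_um
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Long-format degree distributions for a collection of infiltrates
#'
#' @param infiltrates list of `neighborhood_graph` objects.
#' @return data.frame with columns `infiltrate_id`, `k`, `P_k`.
#' @export
degree_table <- function(infiltrates) {
  rows <- lapply(infiltrates, function(g) {
    deg <- degree_statistics(g)
    data.frame(infiltrate_id = g$infiltrate_id,
               k = as.integer(names(deg$P_k)),
               P_k = as.numeric(deg$P_k))
  })
  if (length(rows) == 0) {
    return(data.frame(infiltrate_id = character(0), k = integer(0),
                      P_k = numeric(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
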