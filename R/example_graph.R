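#' Hand-constructed worked-example neighborhood graph
#'
#' A small labelled graph used in the documentation and tests to illustrate
#' the edge-label machinery. Ten B cells form a connected cluster around a hub
#' with six B--B links, two further B cells form an isolated pair, two B cells
#' are B-B-isolated, and twenty T cells attach to the B side through exactly
#' twenty inter-type edges. The resulting gamma composition is: one gamma_6,
#' three gamma_4, four gamma_3, three gamma_2, four gamma_1 and five gamma_0
#' edge(s), so with `A = B`:
#' `kappa(2) = (4 + 3 + 1)/20 = 0.4` and `kappa(5) = 1/20 = 0.05`.
#'
#' The graph is an abstract edge list (cells are laid out on a schematic
#' grid); it is not produced by the circumradius filter.
#'
#' @return A labelled `neighborhood_graph` with `type_a = "B"`.
#' @examples
#' g <- example_neighborhood_graph()
#' kappa_score(g, c(2, 5))
#' @export
example_neighborhood_graph <- function() {
  # B cells: h (hub), b1..b6, c, d1, d2 (c-d1 pair, d2 isolated on the B side)
  b_ids <- c("h", "b1", "b2", "b3", "b4", "b5", "b6", "c", "d1", "d2")
  t_ids <- sprintf("t%02d", 1:20)
  cells <- data.frame(
    cell_id = c(b_ids, t_ids),
    x = c(seq_along(b_ids) * 10, seq_along(t_ids) * 10),
    y = c(rep(0, length(b_ids)), rep(20, length(t_ids))),
    phenotype = c(rep("B", length(b_ids)), rep("T", length(t_ids)))
  )
  id <- stats::setNames(seq_len(nrow(cells)), cells$cell_id)
  bb <- rbind(
    c("h", "b1"), c("h", "b2"), c("h", "b3"),
    c("h", "b4"), c("h", "b5"), c("h", "b6"), # hub degree 6
    c("b1", "b2"), c("b1", "b3"), c("b1", "b4"), # b1 degree 4
    c("b2", "b3"), # b2, b3 degree 3; b4 degree 2; b5, b6 degree 1
    c("c", "d1") # isolated B pair (degree 1 each)
  )
  tb <- rbind(
    c("t01", "h"), # gamma_6
    c("t02", "b1"), c("t03", "b1"), c("t04", "b1"), # gamma_4 x3
    c("t05", "b2"), c("t06", "b2"), c("t07", "b3"), c("t08", "b3"), # gamma_3 x4
    c("t09", "b4"), c("t10", "b4"), c("t11", "b4"), # gamma_2 x3
    c("t12", "b5"), c("t13", "b5"), c("t14", "b6"), c("t15", "b6"), # gamma_1 x4
    c("t16", "d2"), c("t17", "d2"), c("t18", "d2"), # gamma_0 x5 (d2: no B-B edge;
    c("t19", "c2b"), c("t20", "c2b") # placeholder replaced below)
  )
  # last two gamma_0 edges attach to a second B-B-isolated B cell
  cells <- rbind(cells, data.frame(cell_id = "d3", x = 110, y = 0,
                                   phenotype = "B"))
  id <- stats::setNames(seq_len(nrow(cells)), cells$cell_id)
  tb[tb[, 2] == "c2b", 2] <- "d3"
  edges <- rbind(bb, tb)
  g <- new_neighborhood_graph(
    cells = cells,
    edges = data.frame(from = unname(id[edges[, 1]]),
                       to = unname(id[edges[, 2]])),
    roi_id = "example", threshold_px = Inf, type_a = "B",
    resolution_um_per_px = 0.253, infiltrate_id = "example_inf001")
  label_edges(g, "B")
}
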