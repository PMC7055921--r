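#' Read a cell table CSV into a cell map
#'
#' Expected header: `cell_id,x_px,y_px,phenotype` (UTF-8). Rows with missing
#' columns, non-numeric coordinates or phenotypes outside the registry fail
#' with the offending row number; exact coordinate duplicates are resolved by
#' keeping the smallest `cell_id` (with a warning).
#'
#' @param path CSV file path.
#' @param roi_id identifier; default is the file name without extension.
#' @param resolution_um_per_px scan resolution (default 0.253).
#' @param phenotypes allowed phenotype registry.
#' @return A [cell_map()].
#' @export
read_cell_table <- function(path, roi_id = NULL,
                            resolution_um_per_px = 0.253,
                            phenotypes = c("T", "B")) {
  roi_id <- roi_id %||% sub("\\.[^.]*$", "", basename(path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", comment.char = "#")
  required <- c("cell_id", "x_px", "y_px", "phenotype")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    lg_stop(sprintf("%s: missing column(s) %s", path,
                    paste(missing_cols, collapse = ", ")), "lg_bad_input")
  }
  x <- suppressWarnings(as.numeric(raw$x_px))
  y <- suppressWarnings(as.numeric(raw$y_px))
  bad <- which(is.na(x) | is.na(y))
  if (length(bad) > 0) {
    lg_stop(sprintf("%s: non-numeric coordinate in data row %d", path, bad[1]),
            "lg_bad_input")
  }
  bad <- which(!(raw$phenotype %in% phenotypes))
  if (length(bad) > 0) {
    lg_stop(sprintf("%s: unknown phenotype '%s' in data row %d", path,
                    raw$phenotype[bad[1]], bad[1]), "lg_bad_input")
  }
  cell_map(data.frame(cell_id = raw$cell_id, x = x, y = y,
                      phenotype = raw$phenotype),
           roi_id = roi_id, resolution_um_per_px = resolution_um_per_px,
           phenotypes = phenotypes)
}

#' Write a cell map to the standard cell-table CSV
#'
#' @param cm a [cell_map()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(cm, path) {
  stopifnot(inherits(cm, "cell_map"))
  out <- data.frame(cell_id = cm$cells$cell_id, x_px = cm$cells$x,
                    y_px = cm$cells$y, phenotype = cm$cells$phenotype)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read annotation polygons from GeoJSON
#'
#' Accepts a FeatureCollection of Polygon features in pixel coordinates (the
#' same frame as the cell table). The optional feature properties
#' `annotation_id`, `roi_id` and `label` are used when present.
#' Self-intersecting polygons are rejected with their id.
#'
#' @param path GeoJSON file path.
#' @param default_roi_id roi assigned to features without a `roi_id` property.
#' @return List of [annotation_polygon()]s.
#' @export
read_annotations <- function(path, default_roi_id = "roi") {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features else list(gj)
  out <- list()
  for (i in seq_along(feats)) {
    ft <- feats[[i]]
    geom <- ft$geometry %||% ft
    if (!identical(geom$type, "Polygon")) {
      lg_stop(sprintf("%s: feature %d is not a Polygon", path, i), "lg_bad_annotation")
    }
    ring <- geom$coordinates[[1]]
    v <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    props <- ft$properties %||% list()
    out[[length(out) + 1]] <- annotation_polygon(
      v,
      annotation_id = props$annotation_id %||% sprintf("ann%03d", i),
      roi_id = props$roi_id %||% default_roi_id,
      label = props$label)
  }
  out
}

# single polygon -> GeoJSON feature list
polygon_feature <- function(vertices, properties) {
  properties <- properties[!vapply(properties, is.null, TRUE)]
  ring <- lapply(seq_len(nrow(vertices)), function(i) as.numeric(vertices[i, ]))
  ring[[length(ring) + 1]] <- ring[[1]] # close the ring
  list(type = "Feature",
       properties = properties,
       geometry = list(type = "Polygon", coordinates = list(ring)))
}

write_feature_collection <- function(features, path, config = NULL) {
  fc <- list(type = "FeatureCollection", features = features)
  if (!is.null(config)) fc$properties <- list(run_config = unclass(config))
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write annotation polygons to GeoJSON
#'
#' @param annotations list of [annotation_polygon()]s.
#' @param path output path.
#' @param config optional resolved run configuration embedded in the file.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path, config = NULL) {
  feats <- lapply(annotations, function(a) {
    polygon_feature(a$vertices,
                    list(annotation_id = a$annotation_id, roi_id = a$roi_id,
                         label = a$label))
  })
  write_feature_collection(feats, path, config)
}

#' Concave hulls of infiltrates and compartments as GeoJSON
#'
#' One Polygon feature per infiltrate outline, plus (optionally) one per
#' single-phenotype compartment, each with properties `roi_id`,
#' `infiltrate_id`, `compartment_phenotype` (`NA` for whole infiltrates) and
#' `n_cells`. The alpha parameter of the hull defaults to each graph's own
#' circumradius threshold, so hull and graph are mutually consistent.
#'
#' @param infiltrates list of `infiltrate_graph`s.
#' @param path output GeoJSON path.
#' @param alpha_px hull alpha; `NULL` uses each infiltrate's threshold.
#' @param compartments also emit per-compartment hulls (default TRUE).
#' @param config optional resolved run configuration embedded in the file.
#' @return `path`, invisibly.
#' @export
write_hulls <- function(infiltrates, path, alpha_px = NULL,
                        compartments = TRUE, config = NULL) {
  feats <- list()
  for (g in infiltrates) {
    a <- alpha_px %||% g$threshold_px
    hull <- concave_hull(cbind(g$cells$x, g$cells$y), a)
    if (!is.null(hull)) {
      feats[[length(feats) + 1]] <- polygon_feature(
        hull, list(roi_id = g$roi_id, infiltrate_id = g$infiltrate_id,
                   compartment_phenotype = NA, n_cells = nrow(g$cells)))
    }
    if (compartments) {
      for (cp in split_compartments(g)) {
        hull <- concave_hull(cbind(cp$cells$x, cp$cells$y), a)
        if (is.null(hull)) next
        feats[[length(feats) + 1]] <- polygon_feature(
          hull, list(roi_id = g$roi_id, infiltrate_id = g$infiltrate_id,
                     compartment_phenotype = cp$phenotype,
                     n_cells = nrow(cp$cells)))
      }
    }
  }
  write_feature_collection(feats, path, config)
}

#' Lymphocyte density map over a grid of bins
#'
#' @param cm a [cell_map()].
#' @param bin_px square bin side length in pixels.
#' @return Object of class `density_map`: list with `counts` (matrix, rows =
#'   y bins), `x_breaks`, `y_breaks`, `bin_px`. Bin counts sum to the number
#'   of cells.
#' @export
density_map <- function(cm, bin_px) {
  stopifnot(inherits(cm, "cell_map"), bin_px > 0)
  ix <- floor(cm$cells$x / bin_px)
  iy <- floor(cm$cells$y / bin_px)
  x_range <- range(ix); y_range <- range(iy)
  nx <- x_range[2] - x_range[1] + 1
  ny <- y_range[2] - y_range[1] + 1
  counts <- matrix(0L, nrow = ny, ncol = nx)
  for (r in seq_along(ix)) {
    row <- iy[r] - y_range[1] + 1
    col <- ix[r] - x_range[1] + 1
    counts[row, col] <- counts[row, col] + 1L
  }
  structure(
    list(counts = counts,
         x_breaks = (x_range[1]:(x_range[2] + 1)) * bin_px,
         y_breaks = (y_range[1]:(y_range[2] + 1)) * bin_px,
         bin_px = bin_px),
    class = "density_map"
  )
}

#' Propose regions of interest from a lymphocyte density map
#'
#' Bins holding at least `min_count` cells are merged (4-neighborhood) into
#' rectilinear ROI polygons -- the boundary of the union of qualifying bins.
#' Deterministic for a fixed input.
#'
#' @param cm a [cell_map()].
#' @param bin_px bin side length in pixels.
#' @param min_count minimum cells per qualifying bin.
#' @return List of ROIs; each is a list with `polygon` (two-column matrix of
#'   pixel coordinates) and `n_cells` (cells inside the merged bins).
#' @export
density_roi_selection <- function(cm, bin_px, min_count) {
  dm <- density_map(cm, bin_px)
  qual <- which(dm$counts >= min_count, arr.ind = TRUE)
  if (nrow(qual) == 0) return(list())
  key <- paste(qual[, 1], qual[, 2], sep = "_")
  id_of <- stats::setNames(seq_len(nrow(qual)), key)
  # 4-neighborhood adjacency between qualifying bins
  edges <- NULL
  for (d in list(c(0, 1), c(1, 0))) {
    nb_key <- paste(qual[, 1] + d[1], qual[, 2] + d[2], sep = "_")
    hit <- nb_key %in% key
    if (any(hit)) {
      edges <- rbind(edges, cbind(id_of[key[hit]], id_of[nb_key[hit]]))
    }
  }
  ig <- igraph::make_empty_graph(nrow(qual), directed = FALSE)
  if (!is.null(edges)) ig <- igraph::add_edges(ig, t(edges))
  comp <- igraph::components(ig)
  ix <- floor(cm$cells$x / dm$bin_px)
  iy <- floor(cm$cells$y / dm$bin_px)
  cell_key <- paste(iy - floor(min(cm$cells$y / dm$bin_px)) + 1,
                    ix - floor(min(cm$cells$x / dm$bin_px)) + 1, sep = "_")
  lapply(seq_len(comp$no), function(ci) {
    bins <- qual[comp$membership == ci, , drop = FALSE]
    poly <- bin_union_boundary(bins, dm)
    bin_keys <- paste(bins[, 1], bins[, 2], sep = "_")
    list(polygon = poly, n_cells = sum(cell_key %in% bin_keys))
  })
}

# boundary polygon of a union of grid bins (rows = (row, col) indices into a
# density_map); returns pixel coordinates of the outer ring
bin_union_boundary <- function(bins, dm) {
  # corner vertices of each bin, as integer grid coordinates (col, row)
  seg <- NULL
  key <- paste(bins[, 1], bins[, 2], sep = "_")
  for (b in seq_len(nrow(bins))) {
    r <- bins[b, 1]; cl <- bins[b, 2]
    # each side is kept when the neighboring bin across it is absent
    sides <- list(
      list(nb = c(r - 1, cl), v = rbind(c(cl - 1, r - 1), c(cl, r - 1))), # top
      list(nb = c(r + 1, cl), v = rbind(c(cl - 1, r), c(cl, r))), # bottom
      list(nb = c(r, cl - 1), v = rbind(c(cl - 1, r - 1), c(cl - 1, r))), # left
      list(nb = c(r, cl + 1), v = rbind(c(cl, r - 1), c(cl, r))) # right
    )
    for (sd in sides) {
      if (!(paste(sd$nb[1], sd$nb[2], sep = "_") %in% key)) {
        seg <- rbind(seg, c(sd$v[1, ], sd$v[2, ]))
      }
    }
  }
  verts <- unique(rbind(seg[, 1:2], seg[, 3:4]))
  vkey <- paste(verts[, 1], verts[, 2], sep = "_")
  vid <- stats::setNames(seq_len(nrow(verts)), vkey)
  seg_idx <- cbind(vid[paste(seg[, 1], seg[, 2], sep = "_")],
                   vid[paste(seg[, 3], seg[, 4], sep = "_")])
  rings <- chain_rings(seg_idx)
  areas <- vapply(rings, function(rg) abs(polygon_area(verts[rg, 1], verts[rg, 2])), 0)
  ring <- rings[[which.max(areas)]]
  cbind(dm$x_breaks[1] + verts[ring, 1] * dm$bin_px,
        dm$y_breaks[1] + verts[ring, 2] * dm$bin_px)
}

#' Resolved run configuration
#'
#' Collects the tunable parameters of a pipeline run. The resolved
#' configuration is embedded in outputs (as a sidecar JSON for CSVs, as a
#' property for GeoJSON/JSON files) so every result can be traced to its
#' parameters.
#'
#' @param resolution_um_per_px scan resolution.
#' @param threshold_px circumradius cutoff; `NULL` derives it from the
#'   resolution so the physical cutoff (11.385 um) is preserved.
#' @param min_nodes minimum infiltrate size.
#' @param type_a designated phenotype for edge labelling.
#' @param kappa_orders orders of the organization score.
#' @param seed RNG seed.
#' @param ... further named settings stored verbatim.
#' @return Named list of class `run_config`.
#' @export
run_config <- function(resolution_um_per_px = 0.253, threshold_px = NULL,
                       min_nodes = 10, type_a = "B", kappa_orders = c(2, 5),
                       seed = 1, ...) {
  cfg <- list(resolution_um_per_px = resolution_um_per_px,
              threshold_px = threshold_px %||% default_threshold_px(resolution_um_per_px),
              min_nodes = min_nodes, type_a = type_a,
              kappa_orders = kappa_orders, seed = seed, ...)
  stopifnot(cfg$resolution_um_per_px > 0, cfg$threshold_px >= 0,
            cfg$min_nodes >= 1)
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file; keys as in [run_config()].
#' @return A [run_config()].
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' Write a feature table CSV (with configuration sidecar)
#'
#' @param features data.frame from [features_table()].
#' @param path output CSV path.
#' @param config optional [run_config()]; written to `<path>.config.json`.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(features, path, config = NULL) {
  utils::write.csv(features, path, row.names = FALSE, quote = FALSE)
  if (!is.null(config)) {
    jsonlite::write_json(unclass(config), paste0(path, ".config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}
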