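#' Construct a cell map for one region of interest
#'
#' A cell map is the elementary input of the pipeline: one record per detected
#' lymphocyte with pixel coordinates and a phenotype from a two-element
#' registry (by default CD3+ T cells and CD20+ B cells). Coordinates follow the
#' whole-slide-image convention: origin top-left, y increasing downward, units
#' pixels. The scan resolution converts pixel distances to micrometers at
#' reporting boundaries only.
#'
#' Exact duplicate coordinates break the uniqueness of the Delaunay
#' triangulation; among records sharing identical coordinates only the one with
#' the lexicographically smallest `cell_id` is kept, with a warning.
#'
#' @param cells data.frame with columns `cell_id`, `x`, `y`, `phenotype`.
#' @param roi_id identifier of the region of interest / slide.
#' @param resolution_um_per_px scan resolution in micrometers per pixel
#'   (default 0.253, a 40x scan).
#' @param phenotypes the allowed phenotype registry (exactly two labels).
#' @return An object of class `cell_map`: list with elements `roi_id`, `cells`
#'   (validated data.frame) and `resolution_um_per_px`.
#' @export
cell_map <- function(cells, roi_id = "roi",
                     resolution_um_per_px = 0.253,
                     phenotypes = c("T", "B")) {
  stopifnot(is.data.frame(cells))
  required <- c("cell_id", "x", "y", "phenotype")
  missing_cols <- setdiff(required, names(cells))
  if (length(missing_cols) > 0) {
    lg_stop(sprintf("cell table is missing column(s): %s",
                    paste(missing_cols, collapse = ", ")),
            "lg_bad_input")
  }
  if (!is.numeric(resolution_um_per_px) || length(resolution_um_per_px) != 1 ||
      !is.finite(resolution_um_per_px) || resolution_um_per_px <= 0) {
    lg_stop("resolution_um_per_px must be a single positive number", "lg_bad_input")
  }
  if (length(phenotypes) != 2 || anyDuplicated(phenotypes)) {
    lg_stop("phenotype registry must hold exactly two distinct labels", "lg_bad_input")
  }
  cells <- cells[required]
  cells$cell_id <- as.character(cells$cell_id)
  cells$phenotype <- as.character(cells$phenotype)
  if (!is.numeric(cells$x) || !is.numeric(cells$y)) {
    lg_stop("coordinates must be numeric", "lg_bad_input")
  }
  bad <- which(!is.finite(cells$x) | !is.finite(cells$y))
  if (length(bad) > 0) {
    lg_stop(sprintf("non-finite coordinate in row(s): %s",
                    paste(utils::head(bad, 5), collapse = ", ")),
            "lg_bad_input")
  }
  bad <- which(!(cells$phenotype %in% phenotypes))
  if (length(bad) > 0) {
    lg_stop(sprintf("unknown phenotype %s in row %d (registry: %s)",
                    cells$phenotype[bad[1]], bad[1],
                    paste(phenotypes, collapse = ", ")),
            "lg_bad_input")
  }
  if (anyDuplicated(cells$cell_id)) {
    lg_stop("cell_id values must be unique", "lg_bad_input")
  }
  key <- paste(cells$x, cells$y, sep = "_")
  if (anyDuplicated(key)) {
    ord <- order(key, cells$cell_id)
    keep_first <- !duplicated(key[ord])
    dropped <- sum(!keep_first)
    cells <- cells[sort(ord[keep_first]), , drop = FALSE]
    warning(sprintf("dropped %d cell(s) with duplicated coordinates in %s (kept smallest cell_id)",
                    dropped, roi_id), call. = FALSE)
  }
  rownames(cells) <- NULL
  structure(
    list(roi_id = as.character(roi_id), cells = cells,
         resolution_um_per_px = resolution_um_per_px,
         phenotypes = phenotypes),
    class = "cell_map"
  )
}

#' @export
print.cell_map <- function(x, ...) {
  counts <- table(factor(x$cells$phenotype, levels = x$phenotypes))
  cat(sprintf("<cell_map> %s: %d cells (%s), %.3f um/px\n",
              x$roi_id, nrow(x$cells),
              paste(sprintf("%s=%d", names(counts), counts), collapse = ", "),
              x$resolution_um_per_px))
  invisible(x)
}

#' Number of cells in a cell map
#' @param cm a `cell_map`.
#' @return Integer cell count.
#' @export
n_cells <- function(cm) nrow(cm$cells)

# default physical cutoff in micrometers: 45 px at 0.253 um/px
LG_DEFAULT_CUTOFF_UM <- 45 * 0.253

#' Default circumradius threshold in pixels for a given resolution
#'
#' The default cutoff is 45 px at 0.253 um/px; at any other resolution the
#' same physical distance (11.385 um) is converted back to pixels so the
#' cutoff is preserved in tissue units.
#'
#' @param resolution_um_per_px scan resolution.
#' @return Threshold in pixels.
#' @export
default_threshold_px <- function(resolution_um_per_px = 0.253) {
  LG_DEFAULT_CUTOFF_UM / resolution_um_per_px
}
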