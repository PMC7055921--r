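#' Specification of a synthetic infiltrate point pattern
#'
#' Parameters for one simulated region emulating an infiltrate organization
#' class at realistic lymphocyte spacing. Class defaults follow the observed
#' phenomenology: T-cell areas carry about 17 B cells per 100 cells scattered
#' at random; mixed unstructured regions about 35 with independent phenotype
#' assignment; intermediately organized structures concentrate a 60% B-cell
#' majority into a few clumps over a T background; TLO-like structures place
#' the B cells in a dense core disc with a small fraction of interspersed T
#' cells, surrounded by a T-cell mantle.
#'
#' @param class_label one of [infiltrate_classes()].
#' @param n_cells total number of cells (default 250, giving a region of
#'   roughly the area of a typical annotated infiltrate at 8 um spacing).
#' @param b_fraction fraction of B cells; `NULL` uses the class default
#'   (0.17, 0.35, 0.60, 0.60).
#' @param mean_spacing_um target mean nearest-neighbor spacing (default 8 um,
#'   below the 11.385 um physical edge cutoff so intra-infiltrate edges
#'   survive the default filter).
#' @param n_b_clumps number of B-cell clumps (intermediate class, default 3).
#' @param core_radius_um,mantle_width_um TLO-like core disc radius and
#'   T-mantle width; `NULL` derives them from the spacing (core packed at
#'   0.75 x the overall spacing, mantle sized to hold the remaining T cells
#'   at the overall spacing).
#' @param t_interspersed_fraction fraction of T cells inside the TLO core
#'   (default 0.05).
#' @param jitter_um optional Gaussian coordinate jitter (default 0).
#' @param resolution_um_per_px scan resolution (default 0.253).
#' @param seed RNG seed; the generator is deterministic given the spec.
#' @return Object of class `pattern_spec`.
#' @export
pattern_spec <- function(class_label, n_cells = 250, b_fraction = NULL,
                         mean_spacing_um = 8, n_b_clumps = 3,
                         core_radius_um = NULL, mantle_width_um = NULL,
                         t_interspersed_fraction = 0.05, jitter_um = 0,
                         resolution_um_per_px = 0.253, seed = 1) {
  class_label <- match.arg(class_label, infiltrate_classes())
  defaults <- c(T_CELL_AREA = 0.17, MIXED_UNSTRUCTURED = 0.35,
                INTERMEDIATE = 0.60, TLO_LIKE = 0.60)
  b_fraction <- b_fraction %||% unname(defaults[class_label])
  if (n_cells < 10) lg_stop("bad spec: n_cells must be >= 10", "lg_bad_spec")
  if (b_fraction < 0 || b_fraction > 1) lg_stop("bad spec: b_fraction outside [0,1]", "lg_bad_spec")
  if (mean_spacing_um <= 0) lg_stop("bad spec: mean_spacing_um must be > 0", "lg_bad_spec")
  if (t_interspersed_fraction < 0 || t_interspersed_fraction >= 1) {
    lg_stop("bad spec: t_interspersed_fraction outside [0,1)", "lg_bad_spec")
  }
  structure(
    list(class_label = class_label, n_cells = as.integer(n_cells),
         b_fraction = b_fraction, mean_spacing_um = mean_spacing_um,
         n_b_clumps = as.integer(n_b_clumps),
         core_radius_um = core_radius_um, mantle_width_um = mantle_width_um,
         t_interspersed_fraction = t_interspersed_fraction,
         jitter_um = jitter_um,
         resolution_um_per_px = resolution_um_per_px,
         seed = as.integer(seed)),
    class = "pattern_spec"
  )
}

# uniform sample in an annulus r_in <= r < r_out centered at (cx, cy)
runif_annulus <- function(n, r_in, r_out, cx = 0, cy = 0) {
  r <- sqrt(stats::runif(n, r_in^2, r_out^2))
  th <- stats::runif(n, 0, 2 * pi)
  cbind(cx + r * cos(th), cy + r * sin(th))
}

#' Generate a synthetic infiltrate point pattern
#'
#' Places `n_cells` cells in a disc whose radius is chosen so the mean
#' nearest-neighbor spacing of a uniform pattern matches
#' `mean_spacing_um` (for a Poisson pattern of intensity `lambda` the mean
#' nearest-neighbor distance is `0.5 / sqrt(lambda)`). Phenotypes and
#' geometry follow the class (see [pattern_spec()]). Deterministic for a
#' fixed spec.
#'
#' @param spec a [pattern_spec()].
#' @param roi_id identifier; default encodes class and seed.
#' @return A [cell_map()] in pixel coordinates.
#' @export
generate_pattern <- function(spec, roi_id = NULL) {
  stopifnot(inherits(spec, "pattern_spec"))
  n <- spec$n_cells
  s <- spec$mean_spacing_um
  field_r <- 2 * s * sqrt(n / pi) # uniform disc with mean NN spacing ~ s
  roi_id <- roi_id %||% sprintf("sim_%s_s%d", tolower(spec$class_label), spec$seed)
  xy_phen <- with_seed(spec$seed, {
    cls <- spec$class_label
    if (cls %in% c("T_CELL_AREA", "MIXED_UNSTRUCTURED")) {
      xy <- runif_annulus(n, 0, field_r)
      phen <- ifelse(stats::runif(n) < spec$b_fraction, "B", "T")
    } else if (cls == "INTERMEDIATE") {
      n_b <- round(spec$b_fraction * n)
      n_t <- n - n_b
      centers <- runif_annulus(spec$n_b_clumps, 0, 0.6 * field_r)
      clump_sd <- field_r / 6
      assign_c <- sample.int(spec$n_b_clumps, n_b, replace = TRUE)
      xy_b <- cbind(stats::rnorm(n_b, centers[assign_c, 1], clump_sd),
                    stats::rnorm(n_b, centers[assign_c, 2], clump_sd))
      xy <- rbind(xy_b, runif_annulus(n_t, 0, field_r))
      phen <- c(rep("B", n_b), rep("T", n_t))
    } else { # TLO_LIKE
      n_b <- round(spec$b_fraction * n)
      n_core <- min(n, ceiling(n_b / (1 - spec$t_interspersed_fraction)))
      n_core_t <- n_core - n_b
      n_mantle_t <- n - n_core
      core_r <- spec$core_radius_um %||%
        (2 * (0.75 * s) * sqrt(n_core / pi))
      mantle_w <- spec$mantle_width_um %||% {
        outer_r <- sqrt(core_r^2 + n_mantle_t * (2 * s)^2 / pi)
        outer_r - core_r
      }
      if (core_r <= 0 || mantle_w <= 0) {
        lg_stop("bad spec: non-positive TLO core radius or mantle width", "lg_bad_spec")
      }
      xy_core <- runif_annulus(n_core, 0, core_r)
      core_phen <- sample(c(rep("B", n_b), rep("T", n_core_t)))
      xy_mantle <- runif_annulus(n_mantle_t, core_r, core_r + mantle_w)
      xy <- rbind(xy_core, xy_mantle)
      phen <- c(core_phen, rep("T", n_mantle_t))
    }
    if (spec$jitter_um > 0) {
      xy <- xy + matrix(stats::rnorm(2 * n, 0, spec$jitter_um), ncol = 2)
    }
    list(xy = xy, phen = phen)
  })
  # shift to positive pixel coordinates (WSI frame: origin top-left)
  xy_um <- xy_phen$xy
  off <- -apply(xy_um, 2, min) + 2 * s
  cells <- data.frame(
    cell_id = sprintf("c%05d", seq_len(n)),
    x = (xy_um[, 1] + off[1]) / spec$resolution_um_per_px,
    y = (xy_um[, 2] + off[2]) / spec$resolution_um_per_px,
    phenotype = xy_phen$phen
  )
  cm <- cell_map(cells, roi_id = roi_id,
                 resolution_um_per_px = spec$resolution_um_per_px)
  attr(cm, "class_label") <- spec$class_label
  cm
}

#' Generate a balanced labelled cohort of synthetic patterns
#'
#' Per-pattern seeds are derived reproducibly from the master seed, so two
#' calls with the same arguments give identical cohorts.
#'
#' @param n_per_class patterns per organization class.
#' @param seed master seed.
#' @param classes classes to include (default all four).
#' @param ... further arguments passed to [pattern_spec()] (e.g. `n_cells`).
#' @return List with `cell_maps` (list of [cell_map()]s) and `labels`
#'   (data.frame `roi_id`, `class_label`).
#' @export
generate_labeled_cohort <- function(n_per_class, seed = 1,
                                    classes = infiltrate_classes(), ...) {
  stopifnot(n_per_class >= 1)
  n_total <- n_per_class * length(classes)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1, n_total))
  cms <- vector("list", n_total)
  labels <- character(n_total)
  i <- 0
  for (cl in classes) {
    for (r in seq_len(n_per_class)) {
      i <- i + 1
      spec <- pattern_spec(cl, seed = seeds[i], ...)
      cms[[i]] <- generate_pattern(
        spec, roi_id = sprintf("sim_%s_%03d", tolower(cl), r))
      labels[i] <- cl
    }
  }
  list(cell_maps = cms,
       labels = data.frame(roi_id = vapply(cms, function(x) x$roi_id, ""),
                           class_label = labels))
}
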