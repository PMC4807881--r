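# Morphometric indices computed from segmented objects.
#
# The two occupancy indices are the core readouts: the occupied volume index
# (OVI) models vacuoles as spheres from their widest diameter and divides
# their summed volume by a cytoplasmic reference volume; the occupied area
# index (OAI) divides the summed particle area by the cell area on a plane
# or projection.

#' Ellipsoid volume (two conventions)
#'
#' With `a` the equatorial radius and `b` the axial semi-height of an
#' oblate spheroid, the geometric volume is 4/3*pi*a^2*b
#' (`"standard-oblate"`). The protocol this package automates printed the
#' formula as 4/3*pi*a*b^2 (`"as-printed"`, the default), which is the
#' prolate-style arrangement of the same symbols; both are provided because
#' the two conventions only agree on spheres and the original arithmetic
#' cannot be reconstructed.
#'
#' @param a equatorial radius, micrometres.
#' @param b axial semi-height, micrometres.
#' @param variant `"as-printed"` (4/3*pi*a*b^2) or `"standard-oblate"`
#'   (4/3*pi*a^2*b).
#' @return volume in cubic micrometres.
#' @export
ellipsoid_volume <- function(a, b, variant = c("as-printed", "standard-oblate")) {
  variant <- match.arg(variant)
  check_positive(a, "radius a")
  check_positive(b, "height b")
  switch(variant,
         "as-printed" = 4 / 3 * pi * a * b^2,
         "standard-oblate" = 4 / 3 * pi * a^2 * b)
}

#' Sphere volume
#'
#' @param r radius in micrometres (vectorized, `r >= 0`).
#' @return 4/3*pi*r^3.
#' @export
sphere_volume <- function(r) {
  if (any(!is.finite(r)) || any(r < 0)) stop_hq("domain", "radius must be >= 0")
  4 / 3 * pi * r^3
}

#' Configuration of the occupied volume index
#'
#' By default the denominator is the fixed reference cytoplasmic volume of
#' 311.06 um^3, the wild-type average of the original assay, applied to all
#' groups; `per-cell` mode divides by each cell's own ellipsoid volume
#' instead. Vacuoles with radius below `min_radius` (default 1.5 um) are
#' excluded, so a cell with no vacuole at or above threshold scores 0.
#'
#' @param denominator `"fixed"` or `"per-cell"`.
#' @param reference_volume fixed reference cytoplasm volume, um^3.
#' @param min_radius vacuole inclusion threshold, micrometres.
#' @param variant ellipsoid formula variant used in per-cell mode.
#' @return object of class `hq_ovi_config`.
#' @export
ovi_config <- function(denominator = c("fixed", "per-cell"),
                       reference_volume = 311.06, min_radius = 1.5,
                       variant = c("as-printed", "standard-oblate")) {
  denominator <- match.arg(denominator)
  variant <- match.arg(variant)
  check_positive(reference_volume, "reference volume")
  if (min_radius < 0) stop_hq("domain", "min_radius must be >= 0")
  structure(list(denominator = denominator, reference_volume = reference_volume,
                 min_radius = min_radius, variant = variant),
            class = "hq_ovi_config")
}

morph_result <- function(value, kind, cell_id = NA_character_, group = NA_character_) {
  structure(list(value = value, kind = kind, cell_id = cell_id, group = group),
            class = "hq_morph_result")
}

#' @export
print.hq_morph_result <- function(x, ...) {
  cat(sprintf("<%s> %.6g\n", x$kind, x$value))
  invisible(x)
}

#' Occupied volume index (OVI)
#'
#' Sum of the sphere volumes of all vacuoles with radius at or above the
#' inclusion threshold, divided by the reference cytoplasmic volume (fixed
#' wild-type reference by default, or this cell's ellipsoid volume in
#' per-cell mode).
#'
#' @param vacuoles an `hq_vacuole_set` (or data.frame with a `radius`
#'   column).
#' @param cell an `hq_cell_region`; required for per-cell mode.
#' @param cfg an [ovi_config()].
#' @param cell_id,group labels carried into the result.
#' @return `hq_morph_result` with the dimensionless index.
#' @export
ovi <- function(vacuoles, cell = NULL, cfg = ovi_config(),
                cell_id = NA_character_, group = NA_character_) {
  stopifnot(inherits(cfg, "hq_ovi_config"))
  radii <- vacuoles$radius
  num <- sum(sphere_volume(radii[radii >= cfg$min_radius]))
  den <- if (cfg$denominator == "fixed") cfg$reference_volume else {
    if (is.null(cell) || is.null(cell$a_radius) || is.null(cell$b_height))
      stop_hq("domain", "per-cell OVI needs 3-D cell measurements (a, b)")
    ellipsoid_volume(cell$a_radius, cell$b_height, cfg$variant)
  }
  morph_result(num / den, "OVI", cell_id, group)
}

#' Occupied area index (OAI)
#'
#' Summed particle area divided by the cytoplasmic cell area, both in
#' square micrometres; bounded by \[0, 1\] when particles are clipped to the
#' cell mask.
#'
#' @param particles an `hq_particle_set` (or data.frame with `area`, um^2).
#' @param cell_area cytoplasmic area in um^2.
#' @inheritParams ovi
#' @export
oai <- function(particles, cell_area, cell_id = NA_character_, group = NA_character_) {
  check_positive(cell_area, "cell area")
  morph_result(sum(particles$area) / cell_area, "OAI", cell_id, group)
}

#' Lysosomal aggregation index
#'
#' Total particle area divided by particle count, i.e. the mean particle
#' area in um^2 (large values = fewer, larger aggregates).
#'
#' @param particles an `hq_particle_set` with at least one particle.
#' @inheritParams ovi
#' @export
aggregation_index <- function(particles, cell_id = NA_character_, group = NA_character_) {
  if (nrow(particles) == 0L)
    stop_hq("undefined_index", "aggregation index is undefined with no particles")
  morph_result(sum(particles$area) / nrow(particles), "aggregation", cell_id, group)
}

#' Reference mean vesicle diameter of a group of cells
#'
#' Mean over cells of each cell's mean of its `k` largest equivalent
#' diameters; used as the denominator of [diameter_ratio()] so that the
#' reference group self-normalizes to a mean ratio of 1.
#'
#' @param cells list of `hq_particle_set`s (one per cell).
#' @param k vesicles per cell entering the average.
#' @param select `"largest"` (deterministic default) or `"random"`.
#' @param seed seed for random selection.
#' @return mean diameter in micrometres.
#' @export
diameter_reference <- function(cells, k = 3L, select = c("largest", "random"),
                               seed = 1L) {
  select <- match.arg(select)
  per_cell <- vapply(cells, function(p)
    cell_mean_diameter(p, k, select, seed), numeric(1))
  mean(per_cell, na.rm = TRUE)
}

cell_mean_diameter <- function(particles, k, select, seed) {
  d <- particles$eq_diameter
  if (length(d) < k) return(NA_real_)
  picked <- switch(select,
    largest = sort(d, decreasing = TRUE)[seq_len(k)],
    random = with_seed(seed, sample(d, k)))
  mean(picked)
}

#' Per-cell vesicle diameter ratio
#'
#' For each cell, the mean of `k` selected vesicle equivalent diameters
#' divided by the reference group's mean diameter. Cells with fewer than
#' `k` vesicles are flagged with `NA`.
#'
#' @param cells list of `hq_particle_set`s (one per cell).
#' @param reference_mean reference mean diameter (micrometres, > 0),
#'   typically from [diameter_reference()] on the reference genotype.
#' @param k number of vesicles per cell (default 3; the `k` largest by
#'   equivalent diameter are used, a deterministic stand-in for picking
#'   three representative vesicles by hand).
#' @param select `"largest"` or `"random"` (seeded).
#' @param seed seed for random selection.
#' @param group label carried into the results.
#' @return data.frame (cell_id, group, kind, value, flagged).
#' @export
diameter_ratio <- function(cells, reference_mean, k = 3L,
                           select = c("largest", "random"), seed = 1L,
                           group = NA_character_) {
  check_positive(reference_mean, "reference mean diameter")
  select <- match.arg(select)
  vals <- vapply(cells, function(p)
    cell_mean_diameter(p, k, select, seed) / reference_mean, numeric(1))
  data.frame(cell_id = as.character(seq_along(cells)), group = group,
             kind = "diameter-ratio", value = vals, flagged = is.na(vals))
}
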