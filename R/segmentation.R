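# Segmentation of cell bodies, cytoskeletal-void vacuoles and 2-D particles.
#
# Thresholds default to Otsu on the analysed volume/plane, which replaces the
# manual ImageJ binarization of the original workflow with a deterministic
# equivalent; all outputs carry physical units from the stack calibration.

# per-slice hole filling of a 3-D logical mask (vacuole voids are enclosed in
# every z-slice they appear in)
fill_holes_3d <- function(mask3) {
  for (k in seq_len(dim(mask3)[1])) {
    m <- mask3[k, , ]
    if (any(m))
      mask3[k, , ] <- EBImage::fillHull(EBImage::Image(m * 1)) > 0.5
  }
  mask3
}

erode_slicewise <- function(mask3) {
  brush <- EBImage::makeBrush(3, "box")
  for (k in seq_len(dim(mask3)[1])) {
    m <- mask3[k, , ]
    if (any(m))
      mask3[k, , ] <- EBImage::erode(EBImage::Image(m * 1), brush) > 0.5
  }
  mask3
}

#' Segment the cell body from a cytoskeleton channel
#'
#' Otsu-thresholds the channel volume, fills holes slice-wise (so vacuole
#' voids belong to the cell), labels 3-D components (6-connectivity) and
#' keeps the largest (ties broken by lowest label). Reports the cytoplasmic
#' area of the z-projection, the equivalent-circle radius `a` of the widest
#' z-slice and the axial semi-height `b` (half the top-to-bottom mask
#' extent times the z step).
#'
#' @param stack an [image_stack()].
#' @param channel cytoskeleton channel index.
#' @param time frame index for time-lapse stacks.
#' @param min_component_voxels components smaller than this are not counted
#'   as cell candidates.
#' @return object of class `hq_cell_region`: list with `mask2d` (projection
#'   of the cell mask), `mask3d`, `area` (um^2), `a_radius` (um),
#'   `b_height` (um), `ref_plane` (widest slice index), `n_candidates`,
#'   `voxel`.
#' @export
segment_cell_body <- function(stack, channel = 1L, time = 1L,
                              min_component_voxels = 32L) {
  vol <- get_volume(stack, channel, time)
  thr <- tryCatch(otsu_threshold(vol),
                  hq_empty_scene_error = function(e)
                    stop_hq("empty_scene", "no structure in channel %d", channel))
  fg <- vol > thr
  if (!any(fg)) stop_hq("empty_scene", "no foreground after thresholding")
  fg <- fill_holes_3d(fg)
  lab <- label_components(fg, connectivity = 6L)
  sizes <- tabulate(lab[lab > 0])
  cand <- which(sizes >= min_component_voxels)
  if (length(cand) == 0L) stop_hq("empty_scene", "no component above size floor")
  largest <- cand[which.max(sizes[cand])]   # which.max: lowest index on ties
  mask3 <- lab == largest

  vx <- unname(stack$voxel["xy"]); vz <- unname(stack$voxel["z"])
  slice_px <- apply(mask3, 1L, sum)
  ref <- which.max(slice_px)
  a <- sqrt(slice_px[ref] * vx^2 / pi)
  zs <- which(slice_px > 0)
  b <- (max(zs) - min(zs) + 1L) * vz / 2
  mask2 <- apply(mask3, c(2L, 3L), any)

  structure(list(mask2d = mask2, mask3d = mask3,
                 area = sum(mask2) * vx^2,
                 a_radius = a, b_height = b, ref_plane = ref,
                 n_candidates = length(cand), threshold = thr,
                 voxel = stack$voxel),
            class = "hq_cell_region")
}

#' @export
print.hq_cell_region <- function(x, ...) {
  cat(sprintf("<hq_cell_region> area %.2f um^2, a = %.2f um, b = %.2f um (%d candidate component(s))\n",
              x$area, x$a_radius, x$b_height, x$n_candidates))
  invisible(x)
}

# widest in-plane extent of one component across z-slices:
# max pairwise boundary-pixel-centre distance (via convex hull) plus half a
# pixel, a correction calibrated on digitized spheres (see methods vignette)
widest_diameter <- function(mask3, vx) {
  best <- 0
  for (k in seq_len(dim(mask3)[1])) {
    m <- mask3[k, , ]
    if (!any(m)) next
    idx <- which(m, arr.ind = TRUE)
    if (nrow(idx) == 1L) { best <- max(best, vx); next }
    h <- grDevices::chull(idx[, 1], idx[, 2])
    d <- max(stats::dist(idx[h, , drop = FALSE])) * vx
    best <- max(best, d + 0.5 * vx)
  }
  best
}

#' Detect vacuoles as cytoskeletal voids inside a cell
#'
#' Connected sub-threshold regions (6-connectivity) interior to the cell
#' mask (eroded by one pixel to suppress rim artifacts) are candidate
#' vacuoles. Each void's radius is half its widest in-plane diameter across
#' z-slices; voids below `min_radius` are discarded and volumes use the
#' sphere formula, matching the manual widest-point protocol.
#'
#' @param stack an [image_stack()].
#' @param cell an `hq_cell_region` from [segment_cell_body()].
#' @param channel cytoskeleton channel index.
#' @param min_radius minimum vacuole radius in micrometres retained in the
#'   set (the index-level inclusion rule of 1.5 um is applied separately in
#'   [ovi()]; the default here keeps sub-threshold voids visible).
#' @param min_voxels voids smaller than this many voxels are noise and are
#'   dropped before measurement.
#' @param time frame index.
#' @return object of class `hq_vacuole_set`: data.frame with columns
#'   `label, x, y, z` (centroid, micrometres from the image centre),
#'   `radius, volume` plus attribute `voxel`.
#' @export
detect_vacuoles <- function(stack, cell, channel = 1L, min_radius = 0.5,
                            min_voxels = 8L, time = 1L) {
  if (min_radius < 0) stop_hq("domain", "min_radius must be >= 0")
  vol <- get_volume(stack, channel, time)
  thr <- cell$threshold %||% otsu_threshold(vol)
  interior <- erode_slicewise(cell$mask3d)
  voids <- (vol <= thr) & interior
  lab <- label_components(voids, connectivity = 6L)
  n <- max(lab)
  vx <- unname(stack$voxel["xy"]); vz <- unname(stack$voxel["z"])
  axes <- phys_axes(c(z = dim(vol)[1], y = dim(vol)[2], x = dim(vol)[3]),
                    stack$voxel)
  out <- data.frame(label = integer(0), x = numeric(0), y = numeric(0),
                    z = numeric(0), radius = numeric(0), volume = numeric(0))
  keep <- 0L
  for (i in seq_len(n)) {
    comp <- lab == i
    if (sum(comp) < min_voxels) next
    r <- widest_diameter(comp, vx) / 2
    if (r < min_radius) next
    idx <- which(comp, arr.ind = TRUE)
    keep <- keep + 1L
    out[keep, ] <- list(keep,
                        mean(axes$x[idx[, 3]]), mean(axes$y[idx[, 2]]),
                        mean(axes$z[idx[, 1]]),
                        r, sphere_volume(r))
  }
  structure(out, voxel = stack$voxel, class = c("hq_vacuole_set", "data.frame"))
}

#' Particle-analysis filter
#'
#' Area limits may be declared in squared pixels (`"px2"`, the ImageJ
#' default — e.g. "size: 20-Infinity") or squared micrometres (`"um2"`).
#'
#' @param min_area,max_area inclusive area limits in `unit`.
#' @param circularity inclusive `c(lo, hi)` range of 4*pi*A/P^2.
#' @param unit `"px2"` or `"um2"`.
#' @return object of class `hq_particle_filter`.
#' @export
particle_filter <- function(min_area = 20, max_area = Inf,
                            circularity = c(0, 1), unit = c("px2", "um2")) {
  unit <- match.arg(unit)
  if (min_area > max_area) stop_hq("domain", "min_area must be <= max_area")
  if (circularity[1] < 0 || circularity[2] > 1 || circularity[1] > circularity[2])
    stop_hq("domain", "circularity range must satisfy 0 <= lo <= hi <= 1")
  structure(list(min_area = min_area, max_area = max_area,
                 circularity = circularity, unit = unit),
            class = "hq_particle_filter")
}

#' Convert a pixel-unit area filter to physical units
#'
#' @param filter an `hq_particle_filter` declared in `"px2"`.
#' @param pixel_size micrometres per pixel.
#' @return the equivalent filter in `"um2"`.
#' @export
filter_to_um2 <- function(filter, pixel_size) {
  if (filter$unit == "um2") return(filter)
  particle_filter(filter$min_area * pixel_size^2,
                  if (is.finite(filter$max_area)) filter$max_area * pixel_size^2 else Inf,
                  filter$circularity, "um2")
}

# crack-length perimeter: exposed pixel-edge count scaled by pi/4, the
# standard correction that makes digitized discs measure ~2*pi*r
crack_perimeter_px <- function(m) {
  pad <- matrix(FALSE, nrow(m) + 2L, ncol(m) + 2L)
  pad[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] <- m
  edges <- sum(pad & !rbind(pad[-1, ], FALSE)) +
    sum(pad & !rbind(FALSE, pad[-nrow(pad), ])) +
    sum(pad & !cbind(pad[, -1], FALSE)) +
    sum(pad & !cbind(FALSE, pad[, -ncol(pad)]))
  edges * pi / 4
}

#' Particle analysis of a single plane or projection
#'
#' Otsu-binarizes the image, labels 8-connected components and measures
#' area, perimeter (crack length x pi/4), circularity (4*pi*A/P^2 clipped
#' to \[0, 1\]), equivalent-circle diameter and centroid in physical units,
#' then applies the area/circularity filter — the automated counterpart of
#' ImageJ's "Analyze Particles".
#'
#' @param image2d numeric matrix (a plane or [max_project()] output).
#' @param filter an [particle_filter()].
#' @param pixel_size micrometres per pixel.
#' @param threshold binarization threshold; `NULL` uses Otsu. Because Otsu
#'   is computed on the relative histogram, results are invariant to
#'   rescaling intensities by a positive gain.
#' @return object of class `hq_particle_set`: data.frame with `label,
#'   area_px, area, perimeter, circularity, eq_diameter, cy, cx` (centroid,
#'   pixels) and attributes `mask` (binary matrix) and `pixel_size`.
#' @export
detect_particles <- function(image2d, filter = particle_filter(),
                             pixel_size = 0.1, threshold = NULL) {
  empty <- data.frame(label = integer(0), area_px = numeric(0),
                      area = numeric(0), perimeter = numeric(0),
                      circularity = numeric(0), eq_diameter = numeric(0),
                      cy = numeric(0), cx = numeric(0))
  bw <- if (is.null(threshold)) {
    if (diff(range(image2d)) == 0) {
      return(structure(empty, mask = image2d > Inf, pixel_size = pixel_size,
                       class = c("hq_particle_set", "data.frame")))
    }
    image2d > otsu_threshold(image2d)
  } else image2d > threshold
  lab <- label_components(bw, connectivity = 8L)
  n <- max(lab)
  out <- empty
  keep <- 0L
  for (i in seq_len(n)) {
    comp <- lab == i
    apx <- sum(comp)
    a_um <- apx * pixel_size^2
    per <- crack_perimeter_px(comp) * pixel_size
    circ <- min(1, 4 * pi * a_um / per^2)
    area_in_unit <- if (filter$unit == "px2") apx else a_um
    if (area_in_unit < filter$min_area || area_in_unit > filter$max_area) next
    if (circ < filter$circularity[1] || circ > filter$circularity[2]) next
    idx <- which(comp, arr.ind = TRUE)
    keep <- keep + 1L
    out[keep, ] <- list(keep, apx, a_um, per, circ,
                        2 * sqrt(a_um / pi), mean(idx[, 1]), mean(idx[, 2]))
  }
  structure(out, mask = bw, pixel_size = pixel_size,
            class = c("hq_particle_set", "data.frame"))
}
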