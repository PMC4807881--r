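# Phagosome-maturation scoring of time-lapse movies: docking detection,
# ROI-integrated pHrodo intensity, FYVE-coat prevalence, and 3-D bacteria
# counting inside cells.
#
# Single-particle movies are assumed (per-particle analysis). The particle
# channel is binarized per frame (its intensity ramps over the movie, so a
# global threshold would drop the dim early frames); the FYVE channel is
# binarized with one movie-wide threshold, computed within the cell mask
# when one is supplied, so that frames where the coat is absent stay empty
# instead of being binarized against the cytoplasmic background.

# per-frame particle mask: Otsu on this frame's volume, with a minimum
# component size so empty frames do not binarize their noise
particle_mask_volume <- function(movie, channel, t, min_px = 4L) {
  vol <- get_volume(movie, channel, t)
  if (diff(range(vol)) == 0) return(array(FALSE, dim(vol)))
  m <- vol > otsu_threshold(vol)
  if (sum(m) < min_px) array(FALSE, dim(vol)) else m
}

fyve_threshold <- function(movie, fyve_channel, cell = NULL) {
  vals <- if (is.null(cell)) movie$data[fyve_channel, , , , ] else
    sapply(seq_len(n_frames(movie)), function(t)
      get_volume(movie, fyve_channel, t)[cell$mask3d])
  tryCatch(otsu_threshold(vals), hq_empty_scene_error = function(e) Inf)
}

#' ROI specification for intensity measurements
#'
#' @param area ROI area in um^2 (default 0.9). The ROI is a square of side
#'   `round(sqrt(area)/pixel)` pixels centred on the particle centroid, on
#'   the particle's mid plane.
#' @return object of class `hq_roi_spec`.
#' @export
roi_spec <- function(area = 0.9) {
  check_positive(area, "ROI area")
  structure(list(area = area), class = "hq_roi_spec")
}

#' Detect the docking frame of a phagocytosed particle
#'
#' t0 is the first frame at which the thresholded particle mask (max
#' projection) overlaps the cell mask by at least one pixel. A particle
#' that never contacts the cell is returned with `docked = FALSE` (the
#' track is to be excluded, not an error).
#'
#' @param movie an [image_stack()] with a frame interval.
#' @param particle_channel particle (pHrodo) channel index.
#' @param cell an `hq_cell_region` giving the cell mask.
#' @return list(docked, t0) with `t0` the 1-based frame index (NA when
#'   never docked).
#' @export
detect_docking <- function(movie, particle_channel = 2L, cell) {
  for (t in seq_len(n_frames(movie))) {
    pm <- apply(particle_mask_volume(movie, particle_channel, t), c(2L, 3L), any)
    if (any(pm & cell$mask2d)) return(list(docked = TRUE, t0 = t))
  }
  list(docked = FALSE, t0 = NA_integer_)
}

#' Build a single-particle track from a movie
#'
#' Localizes the particle per frame by the intensity-weighted centroid of
#' its per-frame thresholded mask (x-y from all mask voxels, mid plane from
#' the weighted mean z) from the docking frame onwards. Frames where the
#' particle is undetectable are dropped from the track.
#'
#' @inheritParams detect_docking
#' @return object of class `hq_track`: list with `t0`, `docked`,
#'   `frame_interval` (s) and data.frame `frames` (frame, cy, cx, z_mid in
#'   pixel/slice units).
#' @export
track_particle <- function(movie, particle_channel = 2L, cell) {
  if (is.null(movie$frame_interval))
    stop_hq("domain", "movie has no frame interval")
  dk <- detect_docking(movie, particle_channel, cell)
  if (!dk$docked)
    return(structure(list(docked = FALSE, t0 = NA_integer_,
                          frame_interval = movie$frame_interval,
                          frames = NULL), class = "hq_track"))
  rows <- lapply(dk$t0:n_frames(movie), function(t) {
    sel <- particle_mask_volume(movie, particle_channel, t)
    if (!any(sel)) return(NULL)
    vol <- get_volume(movie, particle_channel, t)
    idx <- which(sel, arr.ind = TRUE)
    w <- vol[sel]
    data.frame(frame = t,
               cy = sum(idx[, 2] * w) / sum(w),
               cx = sum(idx[, 3] * w) / sum(w),
               z_mid = round(sum(idx[, 1] * w) / sum(w)))
  })
  structure(list(docked = TRUE, t0 = dk$t0,
                 frame_interval = movie$frame_interval,
                 frames = do.call(rbind, rows)),
            class = "hq_track")
}

#' Per-frame ROI intensity of a tracked particle
#'
#' For every tracked frame, the mean intensity ("average integrated
#' intensity per pixel") over a square ROI of the configured physical area,
#' centred on the rounded particle centroid, on the particle's mid plane.
#' ROIs clipped by the image border are flagged.
#'
#' @param movie an [image_stack()].
#' @param track an `hq_track` from [track_particle()].
#' @param roi an [roi_spec()].
#' @param channel channel measured (defaults to the particle channel 2).
#' @return data.frame (frame, time_min since t0, intensity, clipped).
#' @export
intensity_series <- function(movie, track, roi = roi_spec(), channel = 2L) {
  if (!isTRUE(track$docked)) stop_hq("domain", "track has no docking frame")
  vx <- unname(movie$voxel["xy"])
  side <- max(1L, round(sqrt(roi$area) / vx))
  half_lo <- (side - 1L) %/% 2L
  half_hi <- side - 1L - half_lo
  d <- dim(movie$data)
  out <- track$frames
  out$time_min <- (out$frame - track$t0) * track$frame_interval / 60
  out$intensity <- NA_real_
  out$clipped <- FALSE
  for (i in seq_len(nrow(out))) {
    cy <- round(out$cy[i]); cx <- round(out$cx[i])
    ys <- (cy - half_lo):(cy + half_hi)
    xs <- (cx - half_lo):(cx + half_hi)
    clip <- any(ys < 1 | ys > d[4] | xs < 1 | xs > d[5])
    ys <- ys[ys >= 1 & ys <= d[4]]; xs <- xs[xs >= 1 & xs <= d[5]]
    pl <- get_plane(movie, channel, out$z_mid[i], out$frame[i])
    out$intensity[i] <- mean(pl[ys, xs])
    out$clipped[i] <- clip
  }
  out[, c("frame", "time_min", "intensity", "clipped")]
}

#' FYVE prevalence of a tracked particle
#'
#' A frame counts as FYVE-positive when at least `criterion` of a
#' one-pixel-thick annulus just outside the particle boundary (on the
#' particle's mid plane) lies in the binarized FYVE channel. Prevalence is
#' the positive-frame count converted to minutes by the movie's frame
#' interval. The FYVE threshold is a single movie-wide Otsu threshold,
#' computed within the cell mask when `cell` is given (recommended: it
#' separates the coat from the cytoplasmic FYVE background rather than
#' from the extracellular background).
#'
#' @param movie an [image_stack()].
#' @param track an `hq_track`.
#' @param fyve_channel FYVE channel index.
#' @param criterion fraction of the annulus required, in (0, 1\].
#' @param particle_channel channel defining the particle mask.
#' @param cell optional `hq_cell_region` restricting the FYVE histogram.
#' @return object of class `hq_prevalence`: list(positive_frames,
#'   prevalence_min, per_frame data.frame, criterion, frame_interval).
#' @export
fyve_prevalence <- function(movie, track, fyve_channel = 1L, criterion = 0.5,
                            particle_channel = 2L, cell = NULL) {
  if (!isTRUE(track$docked)) stop_hq("domain", "track has no docking frame")
  if (criterion <= 0 || criterion > 1)
    stop_hq("domain", "criterion must be in (0, 1]")
  fthr <- fyve_threshold(movie, fyve_channel, cell)
  brush <- EBImage::makeBrush(3, "box")
  cov <- numeric(nrow(track$frames))
  for (i in seq_len(nrow(track$frames))) {
    fr <- track$frames$frame[i]; z <- track$frames$z_mid[i]
    pvol <- particle_mask_volume(movie, particle_channel, fr)
    pmask <- pvol[z, , ]
    if (!any(pmask)) { cov[i] <- 0; next }
    # keep the component under the tracked centroid
    lab <- label_components(pmask, 8L)
    cy <- max(1, min(nrow(pmask), round(track$frames$cy[i])))
    cx <- max(1, min(ncol(pmask), round(track$frames$cx[i])))
    want <- lab[cy, cx]
    if (want == 0L) {
      sizes <- tabulate(lab[lab > 0])
      want <- which.max(sizes)
    }
    pmask <- lab == want
    ann <- (EBImage::dilate(EBImage::Image(pmask * 1), brush) > 0.5) & !pmask
    fbin <- get_plane(movie, fyve_channel, z, fr) > fthr
    cov[i] <- mean(fbin[ann])
  }
  pos <- cov >= criterion
  structure(list(positive_frames = sum(pos),
                 prevalence_min = sum(pos) * track$frame_interval / 60,
                 per_frame = data.frame(frame = track$frames$frame,
                                        coverage = cov, positive = pos),
                 criterion = criterion,
                 frame_interval = track$frame_interval),
            class = "hq_prevalence")
}

#' @export
print.hq_prevalence <- function(x, ...) {
  cat(sprintf("<hq_prevalence> %d positive frame(s) = %.2f min (criterion %.2f)\n",
              x$positive_frames, x$prevalence_min, x$criterion))
  invisible(x)
}

#' Count fluorescent spots (bacteria) inside a cell
#'
#' 3-D connected supra-threshold components of the spot channel whose
#' centroid lies inside the 3-D cell mask, size-filtered by a minimum voxel
#' count (spots merged below the resolution limit count once).
#'
#' @param stack an [image_stack()].
#' @param spot_channel channel carrying the spots.
#' @param cell an `hq_cell_region` with a 3-D mask.
#' @param min_voxels minimum component size.
#' @param time frame index.
#' @return integer count.
#' @export
count_spots_in_cell <- function(stack, spot_channel = 2L, cell,
                                min_voxels = 5L, time = 1L) {
  vol <- get_volume(stack, spot_channel, time)
  if (diff(range(vol)) == 0) return(0L)
  lab <- label_components(vol > otsu_threshold(vol), connectivity = 26L)
  n <- max(lab)
  count <- 0L
  for (i in seq_len(n)) {
    idx <- which(lab == i, arr.ind = TRUE)
    if (nrow(idx) < min_voxels) next
    cz <- round(mean(idx[, 1])); cy <- round(mean(idx[, 2])); cx <- round(mean(idx[, 3]))
    if (cell$mask3d[cz, cy, cx]) count <- count + 1L
  }
  count
}
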