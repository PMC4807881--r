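#' Calibrated multi-channel image stack
#'
#' The common currency of all imaging operations: a 5-D intensity array with
#' axis order (channel, time, z, y, x) and physical calibration. Static
#' scenes have a singleton time axis. Pixels are isotropic in x-y
#' (`voxel["xy"]` micrometres per pixel) with an independent z step
#' (`voxel["z"]` micrometres), matching confocal z-stack geometry.
#'
#' @param data numeric array with dimensions (channel, time, z, y, x). A 4-D
#'   array is promoted by inserting a singleton time axis.
#' @param voxel named numeric vector `c(xy =, z =)`, micrometres.
#' @param frame_interval time between frames in seconds, or `NULL` for
#'   static stacks.
#' @param channel_names optional character vector naming the channels.
#' @return an object of class `hq_stack`.
#' @export
image_stack <- function(data, voxel = c(xy = 0.1, z = 0.5),
                        frame_interval = NULL, channel_names = NULL) {
  if (length(dim(data)) == 4L)
    dim(data) <- c(dim(data)[1L], 1L, dim(data)[2:4])
  if (length(dim(data)) != 5L)
    stop_hq("domain", "stack data must have axes (channel, time, z, y, x)")
  check_positive(voxel, "voxel sizes")
  if (!all(c("xy", "z") %in% names(voxel)))
    stop_hq("domain", "voxel must be named c(xy=, z=)")
  if (!is.null(frame_interval)) check_positive(frame_interval, "frame interval")
  structure(list(data = data, voxel = voxel[c("xy", "z")],
                 frame_interval = frame_interval,
                 channel_names = channel_names),
            class = "hq_stack")
}

#' @export
print.hq_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<hq_stack> %d channel(s), %d frame(s), %d z x %d y x %d x; %.3g um/px, %.3g um z-step\n",
    d[1], d[2], d[3], d[4], d[5], x$voxel["xy"], x$voxel["z"]))
  if (!is.null(x$frame_interval))
    cat(sprintf("  frame interval %.4g s\n", x$frame_interval))
  invisible(x)
}

#' @export
dim.hq_stack <- function(x) dim(x$data)

n_channels <- function(stack) dim(stack$data)[1L]
n_frames   <- function(stack) dim(stack$data)[2L]
n_slices   <- function(stack) dim(stack$data)[3L]

check_channel <- function(stack, channel) {
  if (!(channel %in% seq_len(n_channels(stack))))
    stop_hq("domain", "channel %s not present in stack", channel)
  invisible(channel)
}

#' Extract one channel volume
#'
#' @param stack an [image_stack()].
#' @param channel channel index (1-based).
#' @param time frame index (1-based).
#' @return 3-D array (z, y, x).
#' @export
get_volume <- function(stack, channel, time = 1L) {
  check_channel(stack, channel)
  if (!(time %in% seq_len(n_frames(stack))))
    stop_hq("domain", "frame %s out of range", time)
  v <- stack$data[channel, time, , , , drop = FALSE]
  dim(v) <- dim(stack$data)[3:5]
  v
}

#' Extract one z-plane
#'
#' @inheritParams get_volume
#' @param z slice index (1-based).
#' @return matrix (y, x).
#' @export
get_plane <- function(stack, channel, z, time = 1L) {
  v <- get_volume(stack, channel, time)
  if (!(z %in% seq_len(dim(v)[1L]))) stop_hq("domain", "z %s out of range", z)
  m <- v[z, , , drop = FALSE]
  dim(m) <- dim(v)[2:3]
  m
}

#' Maximum-intensity projection over z
#'
#' Pixelwise maximum of all z-slices of one channel, the projection used
#' throughout the area-based (2-D) measurements.
#'
#' @inheritParams get_volume
#' @return matrix (y, x).
#' @export
max_project <- function(stack, channel, time = 1L) {
  v <- get_volume(stack, channel, time)
  apply(v, c(2L, 3L), max)
}

#' Single mid-plane extraction
#'
#' Returns the selected z-plane unchanged; convenience alias of
#' [get_plane()] mirroring the "single confocal z-stack plane across the
#' middle of the particle" measurement rule.
#'
#' @inheritParams get_plane
#' @export
mid_plane <- function(stack, channel, z, time = 1L) get_plane(stack, channel, z, time)

#' Merge two stacks by pixelwise maximum
#'
#' Used to compose scenes (e.g. two cells in one field of view). Stacks must
#' share dimensions and calibration.
#'
#' @param a,b stacks of identical shape and calibration.
#' @return an [image_stack()].
#' @export
merge_stacks <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data)) || !identical(a$voxel, b$voxel))
    stop_hq("domain", "stacks to merge must share shape and calibration")
  image_stack(pmax(a$data, b$data), voxel = a$voxel,
              frame_interval = a$frame_interval)
}

#' Write a stack as multi-page TIFF plus a JSON calibration sidecar
#'
#' Planes are written in (channel, time, z) order as 32-bit float pages;
#' `<prefix>.json` records the axis lengths, calibration and channel names so
#' [read_stack()] can reconstruct the array losslessly.
#'
#' @param stack an [image_stack()].
#' @param prefix output path without extension.
#' @return the TIFF path, invisibly.
#' @export
write_stack <- function(stack, prefix) {
  d <- dim(stack$data)
  # TIFF pages are stored normalized to [0, 1] (32-bit float); the original
  # intensity range lives in the sidecar so reading restores the scale
  rng <- range(stack$data)
  span <- if (rng[2] > rng[1]) rng[2] - rng[1] else 1
  pages <- vector("list", d[1] * d[2] * d[3])
  i <- 0L
  for (ch in seq_len(d[1])) for (t in seq_len(d[2])) for (z in seq_len(d[3])) {
    i <- i + 1L
    pages[[i]] <- (get_plane(stack, ch, z, t) - rng[1]) / span
  }
  tif <- paste0(prefix, ".tif")
  tiff::writeTIFF(pages, tif, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(axes = "ctzyx", shape = as.integer(d),
               intensity_range = rng,
               voxel_um = as.list(stack$voxel),
               frame_interval_s = stack$frame_interval,
               channel_names = stack$channel_names)
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(tif)
}

#' Read a stack written by [write_stack()]
#'
#' @param prefix path prefix used at write time.
#' @return an [image_stack()].
#' @export
read_stack <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(paste0(prefix, ".tif"), all = TRUE)
  d <- as.integer(meta$shape)
  rng <- meta$intensity_range %||% c(0, 1)
  span <- if (rng[2] > rng[1]) rng[2] - rng[1] else 1
  arr <- array(0, d)
  i <- 0L
  for (ch in seq_len(d[1])) for (t in seq_len(d[2])) for (z in seq_len(d[3])) {
    i <- i + 1L
    arr[ch, t, z, , ] <- pages[[i]] * span + rng[1]
  }
  image_stack(arr, voxel = unlist(meta$voxel_um),
              frame_interval = meta$frame_interval_s,
              channel_names = meta$channel_names)
}
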