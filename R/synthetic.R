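# Ground-truthed synthetic data generators.
#
# Every generator is deterministic given its spec + seed and returns the
# analytic ground truth (SceneTruth) alongside the rendered data, so the
# whole downstream pipeline can be validated without microscope data.
#
# Forward model (in order): geometry rendered at voxel resolution ->
# signal-dependent count (Poisson) noise -> additive Gaussian read noise ->
# in-plane Gaussian blur. Parameters live in the spec so tests can switch
# each term off.

#' Specification of a synthetic hemocyte scene
#'
#' The cell body is an oblate spheroid with equatorial semi-axis `a_radius`
#' (micrometres, in the x-y plane) and axial semi-axis `b_height`; with
#' `a_radius == b_height` it reduces to a sphere. Vacuoles are spherical
#' voids punched out of the cytoskeleton channel (channel 1); vesicles are
#' filled spheres or spherical shells rendered into any channel (channel 2
#' by default).
#'
#' @param shape named integer vector `c(z=, y=, x=)`, voxels.
#' @param voxel named numeric vector `c(xy=, z=)`, micrometres per voxel.
#'   The default z step (0.5 um) is the fine end of typical live-cell
#'   confocal z spacing (0.5-1 um).
#' @param a_radius,b_height cell semi-axes in micrometres.
#' @param center_offset cell-centre offset from the image centre,
#'   `c(x=, y=, z=)` micrometres.
#' @param vacuoles `NULL` or data.frame with columns `x, y, z` (offsets from
#'   the cell centre, micrometres) and `radius` (micrometres).
#' @param vesicles `NULL` or data.frame with columns `channel, x, y, z,
#'   diameter, ring, intensity` (`ring` logical: shell instead of filled
#'   sphere; offsets from the cell centre).
#' @param ring_thickness shell thickness for ring vesicles, micrometres.
#' @param signal cytoskeleton signal level (a.u. counts).
#' @param background background level added to all channels.
#' @param noise_rate Poisson count-noise rate (counts per intensity unit);
#'   0 switches count noise off.
#' @param read_noise_sd additive zero-mean Gaussian read noise sd; 0 = off.
#' @param blur_sd in-plane Gaussian blur sd in micrometres; 0 = off.
#' @param seed integer RNG seed.
#' @return validated object of class `hq_scene_spec`.
#' @export
scene_spec <- function(shape = c(z = 24, y = 128, x = 128),
                       voxel = c(xy = 0.1, z = 0.5),
                       a_radius = 5, b_height = 3,
                       center_offset = c(x = 0, y = 0, z = 0),
                       vacuoles = NULL, vesicles = NULL,
                       ring_thickness = 0.3,
                       signal = 100, background = 5,
                       noise_rate = 1, read_noise_sd = 2, blur_sd = 0.15,
                       seed = 1L) {
  check_positive(shape, "image shape")
  check_positive(voxel, "voxel sizes")
  check_positive(c(a_radius, b_height), "cell semi-axes")
  if (noise_rate < 0 || read_noise_sd < 0 || blur_sd < 0)
    stop_hq("domain", "noise and blur parameters must be >= 0")
  if (!is.null(vacuoles)) {
    vacuoles <- as.data.frame(vacuoles)
    check_positive(vacuoles$radius, "vacuole radii")
    for (i in seq_len(nrow(vacuoles))) {
      v <- vacuoles[i, ]
      # conservative containment: sphere centre inside the ellipsoid shrunk
      # by the sphere radius on every semi-axis
      if (v$radius >= min(a_radius, b_height) ||
          (v$x^2 + v$y^2) / (a_radius - v$radius)^2 +
            v$z^2 / (b_height - v$radius)^2 > 1)
        stop_hq("geometry", "vacuole %d (r=%.3g um) extends outside the cell", i, v$radius)
    }
  }
  if (!is.null(vesicles)) {
    vesicles <- as.data.frame(vesicles)
    check_positive(vesicles$diameter, "vesicle diameters")
  }
  structure(list(shape = shape[c("z", "y", "x")], voxel = voxel[c("xy", "z")],
                 a_radius = a_radius, b_height = b_height,
                 center_offset = center_offset[c("x", "y", "z")],
                 vacuoles = vacuoles, vesicles = vesicles,
                 ring_thickness = ring_thickness,
                 signal = signal, background = background,
                 noise_rate = noise_rate, read_noise_sd = read_noise_sd,
                 blur_sd = blur_sd, seed = as.integer(seed)),
            class = "hq_scene_spec")
}

# physical coordinate axes centred on the image
phys_axes <- function(shape, voxel) {
  list(z = (seq_len(shape["z"]) - (shape["z"] + 1) / 2) * voxel["z"],
       y = (seq_len(shape["y"]) - (shape["y"] + 1) / 2) * voxel["xy"],
       x = (seq_len(shape["x"]) - (shape["x"] + 1) / 2) * voxel["xy"])
}

# add a sphere/shell indicator into volume vol [z,y,x]: set (not add)
# intensity where the condition holds
render_sphere <- function(vol, axes, centre, r_inner, r_outer, intensity) {
  for (k in seq_along(axes$z)) {
    dz2 <- (axes$z[k] - centre[3])^2
    if (dz2 > r_outer^2) next
    d2 <- outer((axes$y - centre[2])^2, (axes$x - centre[1])^2, `+`) + dz2
    sel <- d2 <= r_outer^2 & d2 >= r_inner^2
    plane <- vol[k, , ]
    plane[sel] <- intensity
    vol[k, , ] <- plane
  }
  vol
}

apply_noise_blur <- function(arr, spec) {
  # arr: (channel, time, z, y, x)
  if (spec$noise_rate > 0) {
    lam <- pmax(arr * spec$noise_rate, 0)
    arr[] <- stats::rpois(length(arr), lam) / spec$noise_rate
  }
  if (spec$read_noise_sd > 0)
    arr[] <- arr + stats::rnorm(length(arr), 0, spec$read_noise_sd)
  if (spec$blur_sd > 0) {
    sigma_px <- spec$blur_sd / spec$voxel["xy"]
    d <- dim(arr)
    for (ch in seq_len(d[1])) for (t in seq_len(d[2])) for (k in seq_len(d[3])) {
      m <- arr[ch, t, k, , ]
      arr[ch, t, k, , ] <- EBImage::gblur(m, sigma = sigma_px)
    }
  }
  arr
}

#' Render a two-channel hemocyte scene with known geometry
#'
#' Channel 1 carries the cytoskeleton signal filling the cell ellipsoid,
#' with zero-intensity spherical voids at the vacuole positions; channel 2
#' carries the vesicles. The returned truth holds the closed-form volumes
#' of every rendered solid.
#'
#' @param spec a [scene_spec()].
#' @return list with elements `stack` ([image_stack()]) and `truth` (list:
#'   `cytoplasm_volume` = 4/3*pi*a^2*b of the rendered spheroid, `a`, `b`,
#'   `vacuoles` data.frame with analytic sphere volumes, `vesicles`).
#' @export
make_cell_scene <- function(spec) {
  stopifnot(inherits(spec, "hq_scene_spec"))
  with_seed(spec$seed, {
    axes <- phys_axes(spec$shape, spec$voxel)
    d <- c(2L, 1L, unname(spec$shape))
    arr <- array(spec$background, d)
    ctr <- spec$center_offset  # (x, y, z)

    cyto <- array(0, unname(spec$shape))
    for (k in seq_along(axes$z)) {
      e <- outer((axes$y - ctr["y"])^2, (axes$x - ctr["x"])^2, `+`) / spec$a_radius^2 +
        (axes$z[k] - ctr["z"])^2 / spec$b_height^2
      plane <- cyto[k, , ]
      plane[e <= 1] <- spec$signal
      cyto[k, , ] <- plane
    }
    if (!is.null(spec$vacuoles)) {
      for (i in seq_len(nrow(spec$vacuoles))) {
        v <- spec$vacuoles[i, ]
        cyto <- render_sphere(cyto, axes,
                              c(ctr["x"] + v$x, ctr["y"] + v$y, ctr["z"] + v$z),
                              0, v$radius, 0)
      }
    }
    arr[1, 1, , , ] <- arr[1, 1, , , ] + cyto

    if (!is.null(spec$vesicles)) {
      for (i in seq_len(nrow(spec$vesicles))) {
        ve <- spec$vesicles[i, ]
        ch <- if (is.null(ve$channel)) 2L else as.integer(ve$channel)
        vol <- arr[ch, 1, , , ]
        dim(vol) <- unname(spec$shape)
        rin <- if (isTRUE(ve$ring)) max(ve$diameter / 2 - spec$ring_thickness / 2, 0) else 0
        rout <- if (isTRUE(ve$ring)) ve$diameter / 2 + spec$ring_thickness / 2 else ve$diameter / 2
        vol <- render_sphere(vol, axes,
                             c(ctr["x"] + ve$x, ctr["y"] + ve$y, ctr["z"] + ve$z),
                             rin, rout, ve$intensity)
        arr[ch, 1, , , ] <- vol
      }
    }

    arr <- apply_noise_blur(arr, spec)
    stack <- image_stack(arr, voxel = spec$voxel,
                         channel_names = c("cytoskeleton", "vesicles"))

    vac_truth <- if (is.null(spec$vacuoles)) {
      data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                 radius = numeric(0), volume = numeric(0))
    } else {
      cbind(spec$vacuoles,
            volume = sphere_volume(spec$vacuoles$radius))
    }
    ves_truth <- if (is.null(spec$vesicles)) NULL else {
      cbind(spec$vesicles,
            area = pi * (spec$vesicles$diameter / 2)^2,
            volume = sphere_volume(spec$vesicles$diameter / 2))
    }
    truth <- list(cytoplasm_volume = 4 / 3 * pi * spec$a_radius^2 * spec$b_height,
                  a = spec$a_radius, b = spec$b_height,
                  vacuoles = vac_truth, vesicles = ves_truth,
                  seed = spec$seed)
    list(stack = stack, truth = truth)
  })
}

# render a set of 2-D Gaussian puncta onto the (y, x) grid
render_puncta <- function(ny, nx, pos_px, amp, sigma_px) {
  img <- matrix(0, ny, nx)
  w <- ceiling(3 * sigma_px)
  for (i in seq_len(nrow(pos_px))) {
    cy <- pos_px[i, 1]; cx <- pos_px[i, 2]
    ys <- max(1, floor(cy - w)):min(ny, ceiling(cy + w))
    xs <- max(1, floor(cx - w)):min(nx, ceiling(cx + w))
    g <- amp[i] * exp(-(outer((ys - cy)^2, (xs - cx)^2, `+`)) / (2 * sigma_px^2))
    img[ys, xs] <- img[ys, xs] + g
  }
  img
}

#' Render a two-channel punctate scene with controlled channel correlation
#'
#' Builds channel 1 from random Gaussian puncta inside a circular cell and
#' constructs channel 2 as an exact within-mask linear mixture of the
#' channel-1 structure and an orthogonalized independent punctum field, so
#' that before noise the within-mask sample Pearson correlation equals
#' `rho_target` exactly. The truth records the correlation realized on the
#' final (noisy, blurred) image.
#'
#' @param n_puncta number of puncta per channel. Intermediate correlations
#'   (0 < |rho| < 1) need at least 10 puncta to be meaningfully realizable.
#' @param rho_target desired within-mask Pearson correlation, in \[-1, 1\].
#' @param spec a [scene_spec()]; the scene is rendered on a single plane
#'   using the x-y shape, cell radius `a_radius` and the noise model.
#' @return list(stack, truth) with `truth$rho_target`, `truth$rho_realized`
#'   and the cell-mask radius.
#' @export
make_coloc_scene <- function(n_puncta, rho_target, spec = scene_spec()) {
  if (!is.numeric(rho_target) || abs(rho_target) > 1)
    stop_hq("domain", "rho_target must lie in [-1, 1]")
  if (n_puncta < 1)
    stop_hq("domain", "need at least one punctum")
  if (abs(rho_target) > 0 && abs(rho_target) < 1 && n_puncta < 10)
    stop_hq("unreachable_rho",
            "correlation %.2f is not reliably realizable with %d puncta (need >= 10)",
            rho_target, n_puncta)
  with_seed(spec$seed, {
    ny <- unname(spec$shape["y"]); nx <- unname(spec$shape["x"])
    vx <- unname(spec$voxel["xy"])
    cy <- (ny + 1) / 2; cx <- (nx + 1) / 2
    r_px <- spec$a_radius / vx
    mask <- outer((seq_len(ny) - cy)^2, (seq_len(nx) - cx)^2, `+`) <= r_px^2

    draw_positions <- function(n) {
      th <- stats::runif(n, 0, 2 * pi)
      rr <- (r_px - 2) * sqrt(stats::runif(n))
      cbind(cy + rr * sin(th), cx + rr * cos(th))
    }
    sigma_px <- 0.15 / vx
    amp <- function(n) stats::rlnorm(n, log(spec$signal), 0.3)
    p1 <- render_puncta(ny, nx, draw_positions(n_puncta), amp(n_puncta), sigma_px)
    p2 <- render_puncta(ny, nx, draw_positions(n_puncta), amp(n_puncta), sigma_px)

    pedestal <- 0.08 * spec$signal
    a_img <- spec$background + pedestal * mask + p1

    s1 <- p1[mask]
    if (stats::sd(s1) == 0)
      stop_hq("unreachable_rho", "channel-1 structure is constant inside the mask")
    s1 <- (s1 - mean(s1)) / stats::sd(s1)
    q <- rho_target * s1
    if (abs(rho_target) < 1) {
      s2 <- p2[mask]
      s2 <- (s2 - mean(s2)) / stats::sd(s2)
      s2o <- s2 - as.numeric(stats::cor(s1, s2)) * s1   # exact sample orthogonalization
      s2o <- s2o / stats::sd(s2o)
      q <- q + sqrt(1 - rho_target^2) * s2o
    }
    b_vals <- q * stats::sd(p1[mask]) + mean(p1[mask])
    b_img <- matrix(spec$background, ny, nx)
    b_img[mask] <- spec$background + pedestal + b_vals

    arr <- array(0, c(2L, 1L, 1L, ny, nx))
    arr[1, 1, 1, , ] <- a_img
    arr[2, 1, 1, , ] <- b_img
    arr <- apply_noise_blur(arr, spec)
    stack <- image_stack(arr, voxel = spec$voxel,
                         channel_names = c("marker_a", "marker_b"))
    realized <- as.numeric(stats::cor(stack$data[1, 1, 1, , ][mask],
                                      stack$data[2, 1, 1, , ][mask]))
    list(stack = stack,
         truth = list(rho_target = rho_target, rho_realized = realized,
                      mask_radius = spec$a_radius, n_puncta = n_puncta,
                      seed = spec$seed))
  })
}

#' Specification of a synthetic phagocytosis time-lapse
#'
#' One pHrodo-labelled particle docks onto a cell at a known frame, then its
#' intensity follows a logistic acidification ramp while a FYVE-positive
#' shell coats it for a sampled dwell time. Channels: 1 = FYVE (dim
#' cytoplasmic fill + coat ring), 2 = particle (pHrodo).
#'
#' @param shape,voxel,seed as in [scene_spec()].
#' @param frame_interval seconds between frames (live imaging every 90-120 s
#'   is typical; default 120).
#' @param n_frames number of frames (default 45, i.e. 90 min at 120 s).
#' @param cell_a,cell_b cell semi-axes, micrometres.
#' @param particle_diameter micrometres (pHrodo-conjugated bacterial
#'   particle; default 1.5).
#' @param docking_frame ground-truth docking frame t0 (1-based).
#' @param dwell list(family = "truncnorm", mean =, sd =), minutes; the FYVE
#'   coat duration distribution (normal truncated at 0; sd = 0 gives the
#'   mean deterministically).
#' @param ramp list(baseline =, plateau =, t_half =, slope =): logistic
#'   pHrodo intensity ramp, times in minutes after docking.
#' @param ring_thickness FYVE shell thickness, micrometres.
#' @param fyve_intensity,cyto_intensity FYVE coat / cytoplasm levels (a.u.).
#' @param background,noise_rate,read_noise_sd,blur_sd noise model as in
#'   [scene_spec()].
#' @return object of class `hq_timelapse_spec`.
#' @export
timelapse_spec <- function(shape = c(z = 7, y = 72, x = 72),
                           voxel = c(xy = 0.1, z = 0.5),
                           frame_interval = 120, n_frames = 45,
                           cell_a = 2.8, cell_b = 1.6,
                           particle_diameter = 1.5,
                           docking_frame = 6,
                           dwell = list(family = "truncnorm", mean = 20, sd = 5),
                           ramp = list(baseline = 10, plateau = 100,
                                       t_half = 20, slope = 5),
                           ring_thickness = 0.3,
                           fyve_intensity = 80, cyto_intensity = 20,
                           background = 2,
                           noise_rate = 1, read_noise_sd = 1, blur_sd = 0.1,
                           seed = 1L) {
  check_positive(frame_interval, "frame interval")
  check_positive(n_frames, "number of frames")
  check_positive(particle_diameter, "particle diameter")
  check_positive(dwell$mean, "dwell mean")
  if (docking_frame >= n_frames)
    stop_hq("domain", "docking frame must precede the end of the movie")
  structure(list(shape = shape[c("z", "y", "x")], voxel = voxel[c("xy", "z")],
                 frame_interval = frame_interval, n_frames = as.integer(n_frames),
                 cell_a = cell_a, cell_b = cell_b,
                 particle_diameter = particle_diameter,
                 docking_frame = as.integer(docking_frame),
                 dwell = dwell, ramp = ramp,
                 ring_thickness = ring_thickness,
                 fyve_intensity = fyve_intensity, cyto_intensity = cyto_intensity,
                 background = background,
                 noise_rate = noise_rate, read_noise_sd = read_noise_sd,
                 blur_sd = blur_sd, seed = as.integer(seed)),
            class = "hq_timelapse_spec")
}

#' Logistic pHrodo acidification ramp
#'
#' Intensity as a function of time since docking: a logistic rise from
#' `baseline` to `plateau` with half-rise time `t_half` and time constant
#' `slope` (both minutes).
#'
#' @param t_min minutes since docking (vectorized).
#' @param baseline,plateau,t_half,slope ramp parameters.
#' @export
phrodo_ramp <- function(t_min, baseline, plateau, t_half, slope) {
  baseline + (plateau - baseline) / (1 + exp(-(t_min - t_half) / slope))
}

#' Render a phagocytosis time-lapse with known docking and dwell
#'
#' @param spec a [timelapse_spec()].
#' @return list(stack, truth); truth holds `docking_frame`, the sampled
#'   `dwell_min`, `dwell_frames` (rounded to the frame grid),
#'   `dwell_frames_rendered` (after truncation at the movie end, with
#'   `truncated` flag), the docked particle centre (micrometres, image
#'   coordinates) and the ramp parameters.
#' @export
make_timelapse <- function(spec) {
  stopifnot(inherits(spec, "hq_timelapse_spec"))
  with_seed(spec$seed, {
    axes <- phys_axes(spec$shape, spec$voxel)
    nz <- unname(spec$shape["z"])
    d <- c(2L, spec$n_frames, unname(spec$shape))
    arr <- array(spec$background, d)
    pr <- spec$particle_diameter / 2

    # cell centred in the image; docked particle sits inside the cell,
    # pre-docking position is fully outside it
    docked <- c(x = 0.3 * spec$cell_a, y = 0, z = 0)
    outside <- c(x = spec$cell_a + pr + 0.5, y = 0, z = 0)

    # sampled dwell (minutes): normal truncated at zero by rejection
    dwell_min <- if (spec$dwell$sd == 0) spec$dwell$mean else {
      repeat {
        dmn <- stats::rnorm(1, spec$dwell$mean, spec$dwell$sd)
        if (dmn > 0) break
      }
      dmn
    }
    dwell_frames <- round(dwell_min * 60 / spec$frame_interval)
    t0 <- spec$docking_frame
    last_fyve <- t0 + dwell_frames - 1L
    truncated <- last_fyve > spec$n_frames
    rendered <- min(last_fyve, spec$n_frames) - t0 + 1L

    cellvol <- array(spec$background, unname(spec$shape))
    for (k in seq_len(nz)) {
      e <- outer(axes$y^2, axes$x^2, `+`) / spec$cell_a^2 +
        axes$z[k]^2 / spec$cell_b^2
      plane <- cellvol[k, , ]
      plane[e <= 1] <- spec$cyto_intensity
      cellvol[k, , ] <- plane
    }

    for (t in seq_len(spec$n_frames)) {
      fyve <- cellvol
      pos <- if (t >= t0) docked else outside
      tmin <- (t - t0) * spec$frame_interval / 60
      inten <- if (t >= t0)
        phrodo_ramp(tmin, spec$ramp$baseline, spec$ramp$plateau,
                    spec$ramp$t_half, spec$ramp$slope)
      else spec$ramp$baseline
      # set semantics: inside the particle the channel reads the ramp value
      part <- render_sphere(array(spec$background, unname(spec$shape)), axes,
                            c(pos["x"], pos["y"], pos["z"]), 0, pr, inten)
      if (t >= t0 && t - t0 < rendered)
        fyve <- render_sphere(fyve, axes, c(docked["x"], docked["y"], docked["z"]),
                              pr, pr + spec$ring_thickness, spec$fyve_intensity)
      arr[1, t, , , ] <- fyve
      arr[2, t, , , ] <- part
    }

    spec_noise <- list(noise_rate = spec$noise_rate,
                       read_noise_sd = spec$read_noise_sd,
                       blur_sd = spec$blur_sd, voxel = spec$voxel)
    arr <- apply_noise_blur(arr, spec_noise)
    stack <- image_stack(arr, voxel = spec$voxel,
                         frame_interval = spec$frame_interval,
                         channel_names = c("fyve", "phrodo"))
    truth <- list(docking_frame = t0, dwell_min = dwell_min,
                  dwell_frames = dwell_frames,
                  dwell_frames_rendered = rendered, truncated = truncated,
                  particle_centre = docked, particle_diameter = spec$particle_diameter,
                  ramp = spec$ramp, seed = spec$seed)
    list(stack = stack, truth = truth)
  })
}

#' Specification of synthetic organism cohorts
#'
#' @param groups list of group descriptors, each a list with `name`, `n`
#'   (total individuals), `replicates` (vials/tubes; default 1), and either
#'   `lifespan = list(family, median, shape)` for survival cohorts
#'   (`family` one of `"weibull"` — `shape` is the Weibull shape, 1 =
#'   exponential — or `"degenerate"`) or `cfu = list(true_cfu, dilutions,
#'   fraction, spots_per_dilution)` for colony-count cohorts.
#' @param seed integer RNG seed.
#' @return object of class `hq_cohort_spec`.
#' @export
cohort_spec <- function(groups, seed = 1L) {
  if (length(groups) < 1L) stop_hq("domain", "cohort needs at least one group")
  for (g in groups) {
    if (is.null(g$name) || is.null(g$n) || g$n < 1)
      stop_hq("domain", "each group needs a name and n > 0")
    if (!is.null(g$lifespan)) check_positive(g$lifespan$median, "median lifespan")
    if (!is.null(g$cfu)) {
      if (g$cfu$true_cfu < 0) stop_hq("domain", "true CFU must be >= 0")
      if (any(g$cfu$dilutions < 1)) stop_hq("domain", "dilution factors must be >= 1")
    }
  }
  structure(list(groups = groups, seed = as.integer(seed)),
            class = "hq_cohort_spec")
}

split_replicates <- function(n, r) {
  sizes <- rep(n %/% r, r)
  extra <- n %% r
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  sizes
}

#' Simulate per-individual death days
#'
#' Death days are drawn from each group's lifespan distribution and
#' discretized to whole days by ceiling (daily scoring records the first day
#' an individual is found dead). The continuous Weibull is parameterized by
#' its median: scale = median / log(2)^(1/shape).
#'
#' @param spec a [cohort_spec()] whose groups carry `lifespan` fields.
#' @return data.frame (group, replicate, individual_id, death_day).
#' @export
make_survival_cohort <- function(spec) {
  stopifnot(inherits(spec, "hq_cohort_spec"))
  with_seed(spec$seed, {
    rows <- list()
    for (g in spec$groups) {
      ls <- g$lifespan
      if (is.null(ls)) stop_hq("domain", "group %s has no lifespan spec", g$name)
      reps <- g$replicates %||% 1L
      sizes <- split_replicates(g$n, reps)
      idx <- 0L
      for (r in seq_len(reps)) {
        n <- sizes[r]
        days <- switch(ls$family %||% "weibull",
          degenerate = rep(ls$median, n),
          weibull = ,
          exponential = {
            k <- if (identical(ls$family, "exponential")) 1 else (ls$shape %||% 3)
            lambda <- ls$median / log(2)^(1 / k)
            stats::rweibull(n, shape = k, scale = lambda)
          },
          stop_hq("domain", "unknown lifespan family %s", ls$family))
        days <- pmax(1L, as.integer(ceiling(days)))
        rows[[length(rows) + 1L]] <- data.frame(
          group = g$name, replicate = r,
          individual_id = idx + seq_len(n), death_day = days)
        idx <- idx + n
      }
    }
    do.call(rbind, rows)
  })
}

#' Simulate colony counts across a dilution series
#'
#' Each plated spot count is Poisson with mean
#' `true_cfu * fraction / dilution`.
#'
#' @param spec a [cohort_spec()] whose groups carry `cfu` fields.
#' @return data.frame (group, replicate, individual_id, dilution, spot,
#'   count).
#' @export
make_dilution_counts <- function(spec) {
  stopifnot(inherits(spec, "hq_cohort_spec"))
  with_seed(spec$seed, {
    rows <- list()
    for (g in spec$groups) {
      cf <- g$cfu
      if (is.null(cf)) stop_hq("domain", "group %s has no cfu spec", g$name)
      reps <- g$replicates %||% 1L
      sizes <- split_replicates(g$n, reps)
      spots <- cf$spots_per_dilution %||% 1L
      idx <- 0L
      for (r in seq_len(reps)) {
        for (i in seq_len(sizes[r])) {
          idx <- idx + 1L
          for (dil in cf$dilutions) for (s in seq_len(spots)) {
            lam <- cf$true_cfu * (cf$fraction %||% 1) / dil
            rows[[length(rows) + 1L]] <- data.frame(
              group = g$name, replicate = r, individual_id = idx,
              dilution = dil, spot = s,
              count = stats::rpois(1, lam))
          }
        }
      }
    }
    do.call(rbind, rows)
  })
}

#' Draw a randomized cell scene specification
#'
#' Convenience generator used by [run_experiment()]: vacuole radii and
#' vesicle diameters are drawn uniformly from the given ranges and placed
#' without mutual overlap inside the cell (rejection sampling).
#'
#' @param base a [scene_spec()] providing geometry, noise and calibration.
#' @param n_vacuoles,vacuole_radius_range count and range (micrometres) of
#'   vacuole radii; 0 for none.
#' @param n_vesicles,vesicle_diameter_range count and range (micrometres) of
#'   vesicle diameters; 0 for none.
#' @param vesicle_ring logical: render vesicles as rings instead of filled.
#' @param seed integer seed for the draw (the returned spec also carries it).
#' @return a validated [scene_spec()].
#' @export
random_cell_spec <- function(base, n_vacuoles = 0, vacuole_radius_range = c(1.6, 2.4),
                             n_vesicles = 0, vesicle_diameter_range = c(0.8, 1.6),
                             vesicle_ring = FALSE, seed = 1L) {
  with_seed(seed, {
    place <- function(radii, margin = 0.2, wall = 0.25) {
      # `wall` keeps a minimum cytoskeletal shell between each object and the
      # cell surface so voids stay topologically enclosed after voxelization.
      # Greedy sequential placement can dead-end in tight cells, so the whole
      # configuration is resampled on failure.
      for (restart in 1:50) {
        placed <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                             r = numeric(0))
        failed <- FALSE
        for (r in radii) {
          ok <- FALSE
          for (try in 1:200) {
            # uniform inside the shrunken ellipsoid
            ux <- stats::runif(1, -1, 1); uy <- stats::runif(1, -1, 1)
            uz <- stats::runif(1, -1, 1)
            if (ux^2 + uy^2 + uz^2 > 1) next
            re <- r + wall
            cx <- ux * max(base$a_radius - re - 1e-6, 0)
            cy <- uy * max(base$a_radius - re - 1e-6, 0)
            cz <- uz * max(base$b_height - re - 1e-6, 0)
            if ((cx^2 + cy^2) / max(base$a_radius - re, 1e-9)^2 +
                cz^2 / max(base$b_height - re, 1e-9)^2 > 1) next
            if (nrow(placed) > 0) {
              dd <- sqrt((placed$x - cx)^2 + (placed$y - cy)^2 + (placed$z - cz)^2)
              if (any(dd < placed$r + r + margin)) next
            }
            placed <- rbind(placed, data.frame(x = cx, y = cy, z = cz, r = r))
            ok <- TRUE
            break
          }
          if (!ok) { failed <- TRUE; break }
        }
        if (!failed) return(placed)
      }
      stop_hq("geometry", "could not place objects of radii %s inside the cell",
              paste(signif(radii, 3), collapse = ", "))
    }
    vac <- NULL
    if (n_vacuoles > 0) {
      radii <- stats::runif(n_vacuoles, vacuole_radius_range[1], vacuole_radius_range[2])
      p <- place(sort(radii, decreasing = TRUE))
      vac <- data.frame(x = p$x, y = p$y, z = p$z, radius = p$r)
    }
    ves <- NULL
    if (n_vesicles > 0) {
      diams <- stats::runif(n_vesicles, vesicle_diameter_range[1], vesicle_diameter_range[2])
      p <- place(sort(diams, decreasing = TRUE) / 2)
      ves <- data.frame(channel = 2L, x = p$x, y = p$y, z = p$z,
                        diameter = 2 * p$r, ring = vesicle_ring,
                        intensity = base$signal)
    }
    out <- base
    out$vacuoles <- vac
    out$vesicles <- ves
    out$seed <- as.integer(seed)
    # re-validate through the constructor
    do.call(scene_spec, out[setdiff(names(out), character(0))])
  })
}
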