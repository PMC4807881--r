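# shared quiet movie: noise- and blur-free so expectations are analytic
quiet_movie <- function(..., seed = 1L) {
  make_timelapse(timelapse_spec(..., noise_rate = 0, read_noise_sd = 0,
                                blur_sd = 0, seed = seed))
}

test_that("docking is detected at the ground-truth frame", {
  mv <- quiet_movie(docking_frame = 5, n_frames = 12)
  cell <- segment_cell_body(mv$stack, channel = 1, time = 1)
  dk <- detect_docking(mv$stack, cell = cell)
  expect_true(dk$docked)
  expect_equal(dk$t0, 5)

  early <- quiet_movie(docking_frame = 1, n_frames = 8)
  cell1 <- segment_cell_body(early$stack, channel = 1, time = 1)
  expect_equal(detect_docking(early$stack, cell = cell1)$t0, 1)

  # a cell mask far from the particle is never contacted
  off <- cell
  off$mask2d <- matrix(FALSE, nrow(cell$mask2d), ncol(cell$mask2d))
  off$mask2d[1:3, 1:3] <- TRUE
  dk2 <- detect_docking(mv$stack, cell = off)
  expect_false(dk2$docked)
  tr2 <- track_particle(mv$stack, cell = off)
  expect_false(tr2$docked)
})

test_that("ROI intensity is per pixel and follows the generator ramp", {
  # constant channel: series equals the constant for any ROI area
  const <- image_stack(array(4.2, c(2, 6, 3, 30, 30)), frame_interval = 120)
  track <- structure(list(docked = TRUE, t0 = 1, frame_interval = 120,
                          frames = data.frame(frame = 1:6, cy = 15, cx = 15,
                                              z_mid = 2)),
                     class = "hq_track")
  s1 <- intensity_series(const, track, roi_spec(0.9))
  expect_true(all(s1$intensity == 4.2))
  s2 <- intensity_series(const, track, roi_spec(1.8))
  expect_equal(s1$intensity, s2$intensity)

  mv <- quiet_movie(n_frames = 30, docking_frame = 4)
  cell <- segment_cell_body(mv$stack, channel = 1, time = 1)
  tr <- track_particle(mv$stack, cell = cell)
  expect_equal(tr$t0, 4)
  ser <- intensity_series(mv$stack, tr)
  ramp <- mv$truth$ramp
  want <- phrodo_ramp(ser$time_min, ramp$baseline, ramp$plateau,
                      ramp$t_half, ramp$slope)
  expect_true(all(abs(ser$intensity - want) / want < 0.01))
  expect_true(all(diff(ser$intensity) >= -1e-9))   # monotone after docking
  expect_false(any(ser$clipped))
})

test_that("FYVE prevalence bookkeeping is exact on deterministic movies", {
  mv <- quiet_movie(dwell = list(family = "truncnorm", mean = 20, sd = 0),
                    frame_interval = 120, n_frames = 25)
  cell <- segment_cell_body(mv$stack, channel = 1, time = 1)
  tr <- track_particle(mv$stack, cell = cell)
  pv <- fyve_prevalence(mv$stack, tr, cell = cell)
  expect_equal(pv$positive_frames, 10)
  expect_equal(pv$prevalence_min, 20)
  # bookkeeping identity: minutes * 60 / interval is the positive count
  expect_equal(pv$prevalence_min * 60 / pv$frame_interval, pv$positive_frames)

  # blank FYVE channel: prevalence 0
  blank <- mv$stack
  blank$data[1, , , , ] <- 0
  trb <- track_particle(blank, cell = cell)
  pvb <- fyve_prevalence(blank, trb, cell = cell)
  expect_equal(pvb$prevalence_min, 0)
})

test_that("the annulus-coverage criterion separates half-coated particles", {
  mv <- quiet_movie(dwell = list(family = "truncnorm", mean = 20, sd = 0),
                    n_frames = 20)
  cell <- segment_cell_body(mv$stack, channel = 1, time = 1)
  # erase the FYVE ring on ~40% of the image rows -> coverage about 0.6
  half <- mv$stack
  d <- dim(half$data)
  cut <- round(d[4] / 2) - 3
  ring_level <- 25   # above cytoplasm (20), below ring (80)
  for (t in seq_len(d[2])) {
    vol <- half$data[1, t, , , ]
    vol[, 1:cut, ] <- pmin(vol[, 1:cut, ], ring_level)
    half$data[1, t, , , ] <- vol
  }
  tr <- track_particle(half, cell = cell)
  loose <- fyve_prevalence(half, tr, criterion = 0.5, cell = cell)
  strict <- fyve_prevalence(half, tr, criterion = 0.9, cell = cell)
  expect_gt(loose$prevalence_min, 0)
  expect_equal(strict$prevalence_min, 0)
  expect_error(fyve_prevalence(half, tr, criterion = 0), class = "hq_domain_error")
})

test_that("prevalence across noisy movies recovers the dwell distribution", {
  vals <- sapply(1:12, function(sd) {
    mv <- make_timelapse(timelapse_spec(seed = sd))
    cell <- segment_cell_body(mv$stack, channel = 1, time = 1)
    tr <- track_particle(mv$stack, cell = cell)
    c(fyve_prevalence(mv$stack, tr, cell = cell)$prevalence_min,
      mv$truth$dwell_frames * mv$stack$frame_interval / 60)
  })
  # per-movie estimates track the rendered truth to within one frame interval
  expect_true(all(abs(vals[1, ] - vals[2, ]) <= 2))
})

test_that("in-cell spot counting honours the cell boundary and merging", {
  ves <- function(x, y, z) data.frame(channel = 2, x = x, y = y, z = z,
                                      diameter = 0.6, ring = FALSE, intensity = 90)
  inside <- do.call(rbind, list(ves(0, 0, 0), ves(1.5, 0, 0), ves(-1.5, 0.5, 0),
                                ves(0, 1.5, 0.5), ves(0.8, -1.2, -0.5)))
  outside <- do.call(rbind, list(ves(5.6, 0, 0), ves(-5.6, 0, 0), ves(0, 5.6, 0)))
  sp <- quiet_scene(vesicles = rbind(inside, outside))
  sc <- make_cell_scene(sp)
  cell <- segment_cell_body(sc$stack)
  expect_equal(count_spots_in_cell(sc$stack, 2, cell), 5L)

  empty <- quiet_scene()
  sce <- make_cell_scene(empty)
  expect_equal(count_spots_in_cell(sce$stack, 2, segment_cell_body(sce$stack)), 0L)

  # two spots closer than the resolution limit merge into one component
  near <- quiet_scene(vesicles = rbind(ves(0, 0, 0), ves(0.3, 0, 0)))
  scn <- make_cell_scene(near)
  celln <- segment_cell_body(scn$stack)
  expect_lte(count_spots_in_cell(scn$stack, 2, celln), 2L)
  expect_equal(count_spots_in_cell(scn$stack, 2, celln), 1L)
})
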