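test_that("cell-scene truth carries closed-form volumes", {
  # a = b reduces the spheroid to a sphere: V = 4/3 pi 5^3 = 523.5988
  sp <- quiet_scene(shape = c(z = 26, y = 128, x = 128), a_radius = 5, b_height = 5)
  sc <- make_cell_scene(sp)
  expect_equal(sc$truth$cytoplasm_volume, 4 / 3 * pi * 125, tolerance = 1e-12)

  sp2 <- quiet_scene(vacuoles = data.frame(x = 1.5, y = 0, z = 0, radius = 2))
  sc2 <- make_cell_scene(sp2)
  expect_equal(sc2$truth$vacuoles$volume, 4 / 3 * pi * 8, tolerance = 1e-12)
})

test_that("identical spec and seed reproduce the stack bit for bit", {
  sp <- scene_spec(shape = c(z = 6, y = 40, x = 40), a_radius = 1.6,
                   b_height = 1.2, seed = 99)
  s1 <- make_cell_scene(sp)
  s2 <- make_cell_scene(sp)
  expect_identical(s1$stack$data, s2$stack$data)
  sp3 <- scene_spec(shape = c(z = 6, y = 40, x = 40), a_radius = 1.6,
                    b_height = 1.2, seed = 100)
  expect_false(identical(make_cell_scene(sp3)$stack$data, s1$stack$data))
})

test_that("vacuoles outside the cell are rejected at spec time", {
  expect_error(scene_spec(a_radius = 3, b_height = 2,
                          vacuoles = data.frame(x = 2.5, y = 0, z = 0, radius = 1)),
               class = "hq_geometry_error")
  expect_error(scene_spec(vacuoles = data.frame(x = 0, y = 0, z = 0, radius = -1)),
               class = "hq_domain_error")
})

test_that("rendered vacuoles respect the declared calibration", {
  # a radius-2 void must span 2r/voxel +/- 1 px in the noise- and blur-free limit
  sp <- quiet_scene(vacuoles = data.frame(x = 0, y = 0, z = 0, radius = 2))
  sc <- make_cell_scene(sp)
  vol <- get_volume(sc$stack, 1)
  mid <- which.min(abs(seq_len(dim(vol)[1]) - (dim(vol)[1] + 1) / 2))
  row <- vol[mid, round((dim(vol)[2] + 1) / 2), ]
  # void voxels sit at the background level, far below the cytoskeleton
  interior <- 30:100                    # strictly inside the a = 5 um cell
  span <- sum(row[interior] < 50)
  expect_lte(abs(span - 2 * 2 / 0.1), 1)
})

test_that("colocalization generator hits the target correlation", {
  sp <- quiet_scene(shape = c(z = 1, y = 96, x = 96), a_radius = 4)
  mask_r <- function(sc) {
    d <- dim(sc$stack$data)
    cy <- (d[4] + 1) / 2; cx <- (d[5] + 1) / 2
    outer((seq_len(d[4]) - cy)^2, (seq_len(d[5]) - cx)^2, `+`) <= (4 / 0.1)^2
  }
  s1 <- make_coloc_scene(40, 1, sp)
  expect_equal(s1$truth$rho_realized, 1, tolerance = 1e-12)
  sm <- make_coloc_scene(40, -1, sp)
  expect_equal(sm$truth$rho_realized, -1, tolerance = 1e-12)
  s5 <- make_coloc_scene(40, 0.5, sp)
  expect_equal(s5$truth$rho_realized, 0.5, tolerance = 1e-9)

  # rho 0 stays near 0 across seeds
  for (sd in 1:4) {
    sp0 <- quiet_scene(shape = c(z = 1, y = 96, x = 96), a_radius = 4, seed = sd)
    expect_lt(abs(make_coloc_scene(150, 0, sp0)$truth$rho_realized), 0.1)
  }
  expect_error(make_coloc_scene(3, 0.5, sp), class = "hq_unreachable_rho_error")
  expect_error(make_coloc_scene(40, 1.5, sp), class = "hq_domain_error")
})

test_that("realized correlation matches the target for any puncta count", {
  # the mixture is orthogonalized in-sample, so the noise-free realized
  # correlation equals the target exactly at every n (trivial convergence)
  for (n in c(10, 40, 200)) {
    sp <- quiet_scene(shape = c(z = 1, y = 96, x = 96), a_radius = 4, seed = n)
    expect_equal(make_coloc_scene(n, 0.6, sp)$truth$rho_realized, 0.6,
                 tolerance = 1e-9)
  }
  # under the default noise model the realized value is only mildly attenuated
  errs <- sapply(1:5, function(sd) {
    sp <- scene_spec(shape = c(z = 1, y = 96, x = 96), a_radius = 4, seed = sd)
    abs(make_coloc_scene(200, 0.6, sp)$truth$rho_realized - 0.6)
  })
  expect_lt(mean(errs), 0.05)
})

test_that("timelapse truth records dwell and docking geometry", {
  sp <- timelapse_spec(dwell = list(family = "truncnorm", mean = 20, sd = 0),
                       frame_interval = 120, noise_rate = 0,
                       read_noise_sd = 0, blur_sd = 0, seed = 5)
  mv <- make_timelapse(sp)
  expect_equal(mv$truth$dwell_frames, 10)   # 20 min / 2 min per frame
  expect_equal(mv$truth$docking_frame, 6)
  expect_false(mv$truth$truncated)
  # FYVE ring absent before docking: pre-docking FYVE max is the cytoplasm level
  pre_max <- max(mv$stack$data[1, 1:5, , , ])
  expect_lte(pre_max, 20)
  post_max <- max(mv$stack$data[1, 6, , , ])
  expect_gt(post_max, 20)

  long <- timelapse_spec(n_frames = 10, docking_frame = 6,
                         dwell = list(family = "truncnorm", mean = 60, sd = 0),
                         noise_rate = 0, read_noise_sd = 0, blur_sd = 0)
  mvl <- make_timelapse(long)
  expect_true(mvl$truth$truncated)
  expect_equal(mvl$truth$dwell_frames_rendered, 5)
})

test_that("survival cohorts honour the group distributions", {
  deg <- cohort_spec(list(list(name = "g", n = 12, replicates = 3,
                               lifespan = list(family = "degenerate", median = 23))))
  tab <- make_survival_cohort(deg)
  expect_true(all(tab$death_day == 23))
  expect_equal(nrow(tab), 12)
  expect_equal(length(unique(tab$replicate)), 3)

  ex <- cohort_spec(list(list(name = "g", n = 500,
                              lifespan = list(family = "exponential", median = 23))),
                    seed = 21)
  md <- median(make_survival_cohort(ex)$death_day)
  expect_lt(abs(md - 23) / 23, 0.10)

  two <- cohort_spec(list(
    list(name = "a", n = 17, lifespan = list(family = "degenerate", median = 5)),
    list(name = "b", n = 9, lifespan = list(family = "degenerate", median = 7))))
  expect_equal(nrow(make_survival_cohort(two)), 26)
})

test_that("dilution counts follow the sampling expectation", {
  zero <- cohort_spec(list(list(name = "g", n = 10,
                                cfu = list(true_cfu = 0, dilutions = c(1, 10),
                                           fraction = 0.1))))
  expect_true(all(make_dilution_counts(zero)$count == 0))

  big <- cohort_spec(list(list(name = "g", n = 300,
                               cfu = list(true_cfu = 1000, dilutions = 10,
                                          fraction = 0.1))), seed = 8)
  counts <- make_dilution_counts(big)$count
  expect_true(all(counts >= 0 & counts == round(counts)))
  expect_lt(abs(mean(counts) - 10), 1)   # E = 1000 * 0.1 / 10
})
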