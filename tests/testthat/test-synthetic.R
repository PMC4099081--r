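geom_s <- sample_geometry(10, 20)
load_s <- ramp_hold_loading(1, 0.5, 300)

test_that("unconfined generator is exact, seeded and noise-calibrated", {
  g0 <- gen_unconfined_curve(4, c(2, 1), c(1, 10), geom_s, load_s,
                             noise_sd = 0, seed = 5)
  expect_equal(g0$curve$value, g0$truth$clean, tolerance = 1e-12)
  expect_equal(g0$curve$value,
               unconfined_force_relaxation(4, c(2, 1), c(1, 10), geom_s, load_s,
                                           g0$curve$time), tolerance = 1e-12)
  ga <- gen_unconfined_curve(4, c(2, 1), c(1, 10), geom_s, load_s, 2, seed = 5)
  gb <- gen_unconfined_curve(4, c(2, 1), c(1, 10), geom_s, load_s, 2, seed = 5)
  expect_identical(ga$curve$value, gb$curve$value)
  gc_ <- gen_unconfined_curve(4, c(2, 1), c(1, 10), geom_s, load_s, 2, seed = 6)
  expect_false(identical(ga$curve$value, gc_$curve$value))
  # noise calibration at n ~ 1000
  gl <- gen_unconfined_curve(4, c(2, 1), c(1, 10), geom_s,
                             ramp_hold_loading(1, 0.5, 500), noise_sd = 2,
                             seed = 7, sampling_dt = 0.5)
  expect_equal(stats::sd(gl$curve$value - gl$truth$clean), 2, tolerance = 0.1)
})

test_that("confined generator reaches its plateau and hits the T50 oracle", {
  g <- gen_confined_curve(c = 2, settlement_inf = 1.5, h = 5, t_ramp = 1,
                          t_hold = 600, sampling_dt = 0.25, noise_sd = 0, seed = 1)
  expect_equal(g$curve$value[length(g$curve$value)], 1.5, tolerance = 1e-3)
  # reproducibility
  g2 <- gen_confined_curve(2, 1.5, 5, noise_sd = 0.01, seed = 3)
  g3 <- gen_confined_curve(2, 1.5, 5, noise_sd = 0.01, seed = 3)
  expect_identical(g2$curve$value, g3$curve$value)
  # half-consolidation time satisfies c t50 / h^2 = 0.197 within 1%
  t50 <- stats::approx(g$curve$value, g$curve$time - 1, xout = 0.75,
                       ties = "ordered")$y
  expect_equal(2 * t50 / 25, 0.197, tolerance = 0.01)
})

test_that("displacement field evaluators honour their definitions", {
  f0 <- gen_displacement_field("affine", list(A = matrix(0, 2, 2)), n_frames = 5)
  expect_equal(f0(c(10, 20), c(5, 5), 5), cbind(c(0, 0), c(0, 0)))
  fs <- gen_displacement_field("simple-shear", list(gamma = 0.2), n_frames = 11)
  # halfway through the ramp: gamma/2
  expect_equal(fs(0, 10, 6)[1, 1], 0.1 * 10)
  expect_equal(fs(0, 10, 11)[1, 1], 0.2 * 10)
  fb <- gen_displacement_field("bulge", list(amp = 3, x0 = 50, sigma = 8),
                               n_frames = 2)
  # decays below 1% of peak beyond 3 length-scales
  expect_lt(abs(fb(50 + 3.1 * 8, 0, 2)[1, 2]) / 3, 0.01)
  expect_equal(fb(50, 0, 2)[1, 2], -3)
  expect_error(gen_displacement_field("vortex"), "arg")
})

test_that("marker image generator is static under identity and seeded", {
  gm <- gen_marker_images(rows = 3, cols = 3, spacing = 25, origin = c(30, 30),
                          n_frames = 4, nx = 140, ny = 140, seed = 2)
  expect_identical(gm$stack[[1]], gm$stack[[4]])
  expect_equal(gm$truth$trajectories[, , 1], unname(gm$truth$reference))
  gm2 <- gen_marker_images(rows = 3, cols = 3, spacing = 25, origin = c(30, 30),
                           n_frames = 4, nx = 140, ny = 140, noise_sd = 0.02,
                           seed = 2)
  gm3 <- gen_marker_images(rows = 3, cols = 3, spacing = 25, origin = c(30, 30),
                           n_frames = 4, nx = 140, ny = 140, noise_sd = 0.02,
                           seed = 2)
  expect_identical(gm2$stack, gm3$stack)
})

test_that("markers leaving the frame abort with the frame named", {
  f <- gen_displacement_field("affine", list(A = matrix(c(0.5, 0, 0, 0), 2, 2)),
                              n_frames = 6)
  expect_error(gen_marker_images(rows = 3, cols = 3, spacing = 30,
                                 origin = c(60, 60), field = f, n_frames = 6,
                                 nx = 160, ny = 160),
               "frame [0-9]+")
})

test_that("image stacks survive PNG and TIFF round trips", {
  gm <- gen_marker_images(rows = 3, cols = 3, spacing = 25, origin = c(30, 30),
                          n_frames = 3, nx = 120, ny = 120, seed = 4)
  d <- file.path(tempdir(), "stack_png")
  write_image_stack(gm$stack, d, "png")
  back <- read_image_stack(d)
  expect_equal(length(back), 3)
  expect_equal(back[[2]], gm$stack[[2]], tolerance = 1 / 255)
  unlink(d, recursive = TRUE)
  d2 <- file.path(tempdir(), "stack_tif")
  p <- write_image_stack(gm$stack, d2, "tiff")
  back2 <- read_image_stack(p)
  expect_equal(back2[[3]], gm$stack[[3]], tolerance = 1 / 255)
  unlink(d2, recursive = TRUE)
})

test_that("bulge image stacks localise the strain peak near the opening edge", {
  amp <- 6; x0 <- 110; sigma <- 18
  f <- gen_displacement_field("bulge", list(amp = amp, x0 = x0, sigma = sigma),
                              n_frames = 6)
  gm <- gen_marker_images(rows = 7, cols = 9, spacing = 20, origin = c(30, 40),
                          field = f, n_frames = 6, nx = 220, ny = 200,
                          dot_radius = 3, noise_sd = 0, seed = 8)
  res <- suppressMessages(track_strain_pipeline(gm$stack, max_disp = 6))
  prof <- sample_strain_along_line(res$field,
                                   list(from = c(30, 100), to = c(190, 100)),
                                   band_halfwidth = 25, component = "E_xy")
  # ground truth |E_xy| peaks at x0 +/- sigma
  x_peak <- prof$x[which.max(abs(prof$value))]
  expect_lt(min(abs(x_peak - (x0 + c(-1, 1) * sigma))), 20)
})

test_that("coarse marker grids underestimate a localised strain peak", {
  amp <- 6; x0 <- 110; sigma <- 12
  true_peak <- 0.5 * amp / sigma * exp(-0.5)   # small-strain |E_xy| at x0 +/- sigma
  peaks <- sapply(c(40, 16), function(spacing) {
    f <- gen_displacement_field("bulge", list(amp = amp, x0 = x0, sigma = sigma),
                                n_frames = 6)
    nxc <- ceiling(180 / spacing)
    gm <- gen_marker_images(rows = 5, cols = nxc, spacing = spacing,
                            origin = c(25, 50), field = f, n_frames = 6,
                            nx = 230, ny = 220, dot_radius = 3, seed = 9)
    res <- suppressMessages(track_strain_pipeline(gm$stack, max_disp = 6))
    max(abs(res$field$strain[res$field$valid, "E_xy", 6]))
  })
  expect_lt(peaks[1], peaks[2])        # denser grid resolves more of the peak
  expect_lt(peaks[1], 0.9 * true_peak) # coarse grid underestimates the truth
})
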