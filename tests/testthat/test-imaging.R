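make_frame <- function(x, y) {
  structure(list(centroids = data.frame(x = x, y = y,
                                        area = rep(10, length(x)),
                                        darkness = rep(0.5, length(x)))),
            class = "marker_frame")
}

test_that("marker detection finds disk centres to sub-pixel accuracy", {
  gm <- gen_marker_images(rows = 5, cols = 5, spacing = 30, origin = c(40, 40),
                          n_frames = 1, nx = 220, ny = 220, dot_radius = 4,
                          noise_sd = 0, seed = 1)
  mf <- detect_markers(gm$stack[[1]], threshold = 0.5, min_area = 10,
                       max_area = 200)
  expect_equal(nrow(mf$centroids), 25)
  truth <- gm$truth$trajectories[, , 1]
  err <- vapply(seq_len(25), function(i)
    min(sqrt((mf$centroids$x - truth[i, 1])^2 +
             (mf$centroids$y - truth[i, 2])^2)), numeric(1))
  expect_lt(max(err), 0.2)
})

test_that("blank images and area bounds give empty frames with warnings", {
  blank <- matrix(0.9, 100, 100)
  expect_warning(mf <- detect_markers(blank), "no markers")
  expect_equal(nrow(mf$centroids), 0)
  gm <- gen_marker_images(rows = 2, cols = 2, spacing = 40, origin = c(30, 30),
                          n_frames = 1, nx = 120, ny = 120, dot_radius = 3,
                          seed = 1)
  expect_warning(detect_markers(gm$stack[[1]], min_area = 500), "area bounds")
})

test_that("detection count is invariant to moderate Gaussian noise", {
  f <- gen_displacement_field("affine", list(A = matrix(0, 2, 2)))
  counts <- sapply(c(0, 0.02), function(ns) {
    gm <- gen_marker_images(rows = 5, cols = 5, spacing = 30, origin = c(40, 40),
                            field = f, n_frames = 1, nx = 220, ny = 220,
                            dot_radius = 4, noise_sd = ns, seed = 9)
    nrow(detect_markers(gm$stack[[1]], min_area = 10, max_area = 200)$centroids)
  })
  expect_equal(counts[1], counts[2])
})

test_that("a single translating marker yields one complete track", {
  frames <- lapply(0:9, function(f) make_frame(10 + f, 20))
  tr <- link_tracks(frames, max_disp = 5)
  expect_equal(nrow(tr$x), 1)
  expect_true(all(tr$present))
  expect_equal(tr$x[1, ], 10:19)
})

test_that("linking preserves identity on a moving lattice", {
  # 20-marker lattice stepping 0.3 * spacing per frame: >= 99% correct links
  spacing <- 20
  gx <- spacing * (1:5); gy <- spacing * (1:4)
  ref <- as.matrix(expand.grid(x = gx, y = gy))
  nf <- 8
  frames <- lapply(seq_len(nf), function(f)
    make_frame(ref[, 1] + 0.3 * spacing * (f - 1), ref[, 2]))
  tr <- link_tracks(frames, max_disp = 0.5 * spacing)
  expect_equal(nrow(tr$x), 20)
  correct <- 0
  for (i in seq_len(20)) for (f in seq_len(nf))
    correct <- correct + (abs(tr$x[i, f] - (ref[i, 1] + 0.3 * spacing * (f - 1))) < 1e-9 &&
                          abs(tr$y[i, f] - ref[i, 2]) < 1e-9)
  expect_gte(correct / (20 * nf), 0.99)
})

test_that("a marker absent in a middle frame keeps its track with a gap", {
  xs <- 10 + 0:5
  frames <- lapply(seq_along(xs), function(f)
    if (f == 3) make_frame(numeric(), numeric()) else make_frame(xs[f], 15))
  tr <- link_tracks(frames, max_disp = 5, memory = 2)
  expect_equal(nrow(tr$x), 1)
  expect_false(tr$present[1, 3])
  expect_equal(sum(tr$present[1, ]), 5)
  expect_equal(tr$x[1, 6], 15)
})

test_that("track filtering removes short tracks and smoothing is exact on quadratics", {
  nf <- 10
  t <- seq_len(nf)
  # track A: full quadratic; track B: present in 40% of frames only
  xa <- 5 + 2 * t + 0.3 * t^2; ya <- 100 - t
  xb <- rep(50, nf); yb <- rep(60, nf)
  frames <- lapply(t, function(f)
    if (f <= 4) make_frame(c(xa[f], xb[f]), c(ya[f], yb[f]))
    else make_frame(xa[f], ya[f]))
  tr <- link_tracks(frames, max_disp = 20)
  sm <- filter_and_smooth_tracks(tr, min_fraction = 0.5)
  expect_equal(nrow(sm$x), 1)            # 40%-presence track removed
  expect_equal(sm$x[1, ], xa, tolerance = 1e-9)
  expect_equal(sm$y[1, ], ya, tolerance = 1e-9)
})

test_that("polynomial smoothing reduces noise on quadratic trajectories", {
  nf <- 100; t <- seq_len(nf)
  truth <- 20 + 0.5 * t + 0.01 * t^2
  set.seed(31)
  rmse_raw <- rmse_sm <- numeric(20)
  for (r in 1:20) {
    noisy <- truth + rnorm(nf, 0, 0.5)
    frames <- lapply(t, function(f) make_frame(noisy[f], 50))
    sm <- filter_and_smooth_tracks(link_tracks(frames, max_disp = 10), 0.5)
    rmse_raw[r] <- sqrt(mean((noisy - truth)^2))
    rmse_sm[r] <- sqrt(mean((sm$x[1, ] - truth)^2))
  }
  expect_true(all(rmse_sm < rmse_raw))
})

test_that("triangulation matches expected counts and Delaunay property", {
  sq <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  expect_equal(nrow(triangulate(sq)), 2)
  tri1 <- rbind(c(0, 0), c(1, 0), c(0, 1))
  expect_equal(nrow(triangulate(tri1)), 1)
  set.seed(41)
  pts <- cbind(runif(50) * 100, runif(50) * 100)
  tm <- triangulate(pts)
  expect_false(circumcircle_violated(pts, tm, tol = 1e-9))
  expect_error(triangulate(cbind(1:5, 2 * (1:5) + 3)), "collinear")
})

test_that("strain of rigid motions is zero and affine maps are exact", {
  set.seed(51)
  pts <- cbind(runif(30) * 80, runif(30) * 80)
  tm <- triangulate(pts)
  # rigid translation
  sf <- compute_strain_field(tm, pts, pts + 7)
  expect_lt(max(abs(sf$strain), na.rm = TRUE), 1e-12)
  # rigid rotation by 5 degrees: Green-Lagrange exactly objective
  th <- 5 * pi / 180
  Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  sf2 <- compute_strain_field(tm, pts, pts %*% t(Rm))
  expect_lt(max(abs(sf2$strain), na.rm = TRUE), 1e-9)
  # uniform stretch: E_xx = a + a^2/2 on every triangle
  a <- 0.1; b <- -0.05
  disp <- cbind(pts[, 1] * (1 + a), pts[, 2] * (1 + b))
  sf3 <- compute_strain_field(tm, pts, disp)
  v <- sf3$valid
  expect_equal(unname(sf3$strain[v, 1, 1]), rep(a + a^2 / 2, sum(v)),
               tolerance = 1e-12)
  expect_equal(unname(sf3$strain[v, 2, 1]), rep(b + b^2 / 2, sum(v)),
               tolerance = 1e-12)
  expect_lt(max(abs(sf3$strain[v, 3, 1])), 1e-12)
  # simple shear: E_xy = gamma/2, E_yy = gamma^2/2
  g <- 0.1
  sf4 <- compute_strain_field(tm, pts, cbind(pts[, 1] + g * pts[, 2], pts[, 2]))
  expect_equal(unname(sf4$strain[v, 3, 1]), rep(g / 2, sum(v)), tolerance = 1e-12)
  expect_equal(unname(sf4$strain[v, 2, 1]), rep(g^2 / 2, sum(v)), tolerance = 1e-12)
  # small-strain option drops the quadratic terms
  sf5 <- compute_strain_field(tm, pts, disp, measure = "small")
  expect_equal(unname(sf5$strain[v, 1, 1]), rep(a, sum(v)), tolerance = 1e-12)
})

test_that("affine strain is triangulation-independent", {
  pts <- as.matrix(expand.grid(x = 10 * (0:4), y = 10 * (0:4)))
  a <- 0.08
  disp <- cbind(pts[, 1] * (1 + a), pts[, 2])
  tm1 <- triangulate(pts)
  # alternative triangulation: split each lattice quad the other way
  alt <- list()
  for (i in 1:4) for (j in 1:4) {
    n00 <- (j - 1) * 5 + i; n10 <- n00 + 1; n01 <- n00 + 5; n11 <- n01 + 1
    alt[[length(alt) + 1]] <- c(n00, n10, n01)
    alt[[length(alt) + 1]] <- c(n10, n11, n01)
  }
  tm2 <- do.call(rbind, alt)
  s1 <- compute_strain_field(tm1, pts, disp)
  s2 <- compute_strain_field(tm2, pts, disp)
  expect_equal(unname(s1$strain[s1$valid, 1, 1]),
               rep(a + a^2 / 2, sum(s1$valid)), tolerance = 1e-12)
  expect_equal(unname(s2$strain[s2$valid, 1, 1]),
               rep(a + a^2 / 2, sum(s2$valid)), tolerance = 1e-12)
})

test_that("degenerate triangles are flagged invalid", {
  pts <- rbind(c(0, 0), c(10, 0), c(5, 8), c(5.000001, 8.000001))
  tm <- rbind(c(1, 2, 3), c(3, 4, 1))
  expect_message(sf <- compute_strain_field(tm, pts, pts * 1.1), "degenerate")
  expect_true(sf$valid[1])
  expect_false(sf$valid[2])
  expect_true(all(is.na(sf$strain[2, , 1])))
})

test_that("line sampling returns ordered profiles and fails on empty bands", {
  pts <- as.matrix(expand.grid(x = 10 * (0:5), y = 10 * (0:5)))
  tm <- triangulate(pts)
  sf <- compute_strain_field(tm, pts, cbind(pts[, 1] * 1.1, pts[, 2]))
  prof <- sample_strain_along_line(sf, list(from = c(0, 25), to = c(50, 25)),
                                   band_halfwidth = 6, component = "E_xx")
  expect_true(all(diff(prof$s) >= 0))
  expect_equal(prof$value, rep(0.1 + 0.005, nrow(prof)), tolerance = 1e-12)
  expect_error(sample_strain_along_line(sf, list(from = c(0, 500), to = c(50, 500)),
                                        band_halfwidth = 3), "band")
})
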