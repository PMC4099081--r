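test_that("graded mesh respects counts, refinement and opening resolution", {
  geo <- craniectomy_geometry(40, 25, a_c = 12, R_f = 3)
  # uniform refinement: regular grid with nr*nz elements
  mu <- build_dc_mesh(geo, list(fine = 2.5, far = 2.5))
  expect_equal(mu$n_elem, mu$nr * mu$nz)
  # near-uniform grid: cells never exceed the requested size and stay within
  # a factor ~2 of each other (boundary clipping merges runt cells)
  expect_lte(max(diff(mu$rb)), 2.5 * 1.301)
  expect_gte(min(diff(mu$rb)), 2.5 * 0.5)
  expect_lte(max(diff(mu$zb)), 2.5 * 1.301)
  # halving the fine size strictly increases the element count
  m1 <- build_dc_mesh(geo, list(fine = 2, far = 6))
  m2 <- build_dc_mesh(geo, list(fine = 1, far = 6))
  expect_gt(m2$n_elem, m1$n_elem)
  # too-coarse refinement cannot resolve the opening
  expect_error(build_dc_mesh(craniectomy_geometry(40, 25, a_c = 4, R_f = 0),
                             list(fine = 3, far = 12)), "fewer than 4")
})

test_that("all element Jacobians are positive over random valid geometries", {
  set.seed(21)
  for (i in 1:15) {
    R <- runif(1, 20, 80); H <- runif(1, 15, 60)
    a_c <- runif(1, 0.2, 0.6) * R
    R_f <- runif(1, 0, 0.8) * (R - a_c)
    geo <- craniectomy_geometry(R, H, a_c, R_f)
    mesh <- build_dc_mesh(geo, list(fine = R / 25, far = R / 6))
    expect_true(all(mesh_jacobians(mesh) > 0))
    expect_true(all(diff(mesh$rb) > 0) && all(diff(mesh$zb) > 0))
  }
})

test_that("geometry constructor enforces its invariants", {
  expect_error(craniectomy_geometry(40, 25, a_c = 45, R_f = 0), "a_c")
  expect_error(craniectomy_geometry(40, 25, a_c = 10, R_f = 31), "R_f")
  expect_silent(craniectomy_geometry(40, 25, a_c = 0, R_f = 0))
})

test_that("uniform uniaxial compression passes the patch test", {
  # full-width platen on a laterally confined, effectively drained column
  mat <- poroelastic_params(E = 20, nu = 0.3, k = 1e6)
  cfg <- dc_config(craniectomy_geometry(30, 20, a_c = 0, R_f = 0),
                   mat, prony_series(), ramp_hold_loading(1, 1, 5),
                   mesh_refinement = list(fine = 3, far = 7))
  h <- run_dc_simulation(cfg)
  n <- length(h$times)
  ezz <- h$strain[, "e_zz", n]
  expect_equal(max(abs(ezz + 1 / 20)), 0, tolerance = 1e-6)
  expect_lt(max(abs(h$strain[, "e_rr", n])), 1e-9)
  expect_lt(max(abs(h$strain[, "e_rz", n])), 1e-9)
  # sampled strain is uniform too
  prof <- sample_strain(h, list(from = c(2, 10), to = c(25, 10)),
                        time = max(h$times))
  expect_equal(prof$e_zz, rep(-0.05, 100), tolerance = 1e-6)
})

test_that("near-zero platen displacement produces near-zero response", {
  dm <- dc_demo_material()
  cfg <- dc_config(craniectomy_geometry(40, 25, 12, 3), dm$material, dm$prony,
                   ramp_hold_loading(u_max = 1e-9, t_ramp = 2, t_hold = 20),
                   mesh_refinement = list(fine = 2.5, far = 8))
  h <- run_dc_simulation(cfg)
  expect_lt(max(abs(h$platen_load)), 1e-4)
  expect_lt(max(abs(h$P)), 1e-6)
})

test_that("FE column reproduces the Terzaghi solution", {
  qc <- quick_column()
  U_fe <- qc$col$settlement / qc$col$settlement[length(qc$times)]
  U_an <- terzaghi_consolidation(qc$c * qc$times / qc$h^2)
  sel <- qc$times > 0
  l2 <- sqrt(mean((U_fe[sel] - U_an[sel])^2)) / sqrt(mean(U_an[sel]^2))
  expect_lt(l2, 0.02)
  # instantaneous settlement matches the undrained (incompressible) solution:
  # zero, within 5% of the final settlement
  expect_lt(qc$col$settlement[2] / qc$col$settlement[length(qc$times)], 0.05)
})

test_that("time refinement reduces the consolidation oracle error", {
  err <- sapply(c(40, 80), function(ns) {
    qc <- quick_column(n_steps = ns)
    U_fe <- qc$col$settlement / qc$col$settlement[length(qc$times)]
    U_an <- terzaghi_consolidation(qc$c * qc$times / qc$h^2)
    sel <- qc$times > 0
    sqrt(mean((U_fe[sel] - U_an[sel])^2)) / sqrt(mean(U_an[sel]^2))
  })
  expect_lt(err[2], err[1])
})

test_that("boundary outflow balances the settlement volume", {
  qc <- quick_column()
  out <- boundary_fluid_volume(qc$col)
  expect_true(all(diff(out$outflow_mm3) >= -1e-9))
  total <- out$outflow_mm3[nrow(out)]
  vol <- qc$col$settlement[length(qc$times)] * pi * qc$col$radius^2
  expect_equal(total / vol, 1, tolerance = 0.02)
})

test_that("impermeable runs report zero outflow with a notice", {
  dm <- dc_demo_material()
  cfg <- dc_config(craniectomy_geometry(40, 25, 12, 3), dm$material, dm$prony,
                   ramp_hold_loading(2, 2, 20), pore_bc = "impermeable",
                   mesh_refinement = list(fine = 2.5, far = 8))
  h <- run_dc_simulation(cfg)
  expect_message(out <- boundary_fluid_volume(h), "impermeable")
  expect_true(all(out$outflow_mm3 == 0))
})

test_that("drained viscoelastic load history has ramp-corrected Prony form", {
  # full-width platen, conductivity so large the response is always drained:
  # the load history must be fit by the closed-form relaxation with R^2 > 0.999
  mat <- poroelastic_params(E = 20, nu = 0.3, k = 1e5)
  prony <- prony_series(g = c(0.3, 0.15), tau = c(1, 10))
  loading <- ramp_hold_loading(u_max = 1, t_ramp = 2, t_hold = 80)
  cfg <- dc_config(craniectomy_geometry(30, 20, 0, 0), mat, prony, loading,
                   mesh_refinement = list(fine = 3, far = 7),
                   times = c(seq(0, 2, by = 0.1), 2 + cumsum(0.2 * 1.15^(0:24))))
  h <- run_dc_simulation(cfg)
  keep <- h$times >= loading$t_ramp
  curve <- relaxation_curve(h$times[keep], h$platen_load[keep],
                            "unconfined-force", sample_geometry(20, 60), loading)
  fit <- fit_unconfined(curve, n_terms = 2, seed = 1)
  r2 <- 1 - sum((curve$value - fit$fitted)^2) /
    sum((curve$value - mean(curve$value))^2)
  expect_gt(r2, 0.999)
  # recovered time constants close to the generating spectrum
  expect_equal(fit$tau, c(1, 10), tolerance = 0.1)
})

test_that("shear strain localises under the craniectomy edge", {
  h <- run_dc_simulation(quick_dc_config())
  geo <- h$config$geometry
  fine <- h$config$mesh_refinement$fine
  z <- geo$cyl_height - 0.75 * fine
  prof <- sample_strain(h, list(from = c(0, z), to = c(geo$cyl_radius, z)),
                        time = max(h$times), n = 200)
  r_peak <- prof$r[which.max(abs(prof$e_rz))]
  expect_gte(r_peak, geo$a_c - 2 * fine)
  expect_lte(r_peak, geo$a_c + geo$R_f + 2 * fine)
  # line outside the domain fails
  expect_error(sample_strain(h, list(from = c(0, 30), to = c(10, 30)),
                             time = 1), "outside")
  expect_error(sample_strain(h, list(from = c(0, 5), to = c(10, 10)),
                             time = 1), "axis-aligned")
})

test_that("equal-order interpolation request triggers the inf-sup warning", {
  dm <- dc_demo_material()
  expect_warning(
    dc_config(craniectomy_geometry(40, 25, 12, 3), dm$material, dm$prony,
              ramp_hold_loading(2, 2, 20), equal_order = TRUE),
    "inf-sup")
})

test_that("mesh exports to a readable VTK file", {
  mesh <- build_dc_mesh(craniectomy_geometry(40, 25, 12, 3),
                        list(fine = 3, far = 9))
  path <- file.path(tempdir(), "mesh.vtk")
  write_mesh_vtk(mesh, path)
  lines <- readLines(path)
  expect_equal(lines[1], "# vtk DataFile Version 3.0")
  expect_true(any(grepl(sprintf("POINTS %d double", mesh$n_pnodes), lines)))
  expect_true(any(grepl(sprintf("CELLS %d", mesh$n_elem), lines)))
  unlink(path)
})
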