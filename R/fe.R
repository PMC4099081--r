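# Axisymmetric quasi-static finite elements for linear poro-viscoelasticity:
# Biot consolidation (mixed u/p, Taylor-Hood Q9/Q4) with Prony solid
# relaxation integrated by the internal-variable exponential update, backward
# Euler in time.
#
# Because the same Prony spectrum scales shear and bulk moduli (g_i = k_i),
# the constitutive update collapses to scalar factors on a single elastic
# stiffness K0: per step,
#   sigma^{n+1} = gamma(dt) D eps^{n+1} + sum_i e_i h_i^n - (sum_i g_i b_i) D eps^n
# with b_i = (tau_i/dt)(1 - e^{-dt/tau_i}), e_i = e^{-dt/tau_i},
# gamma = g_inf + sum_i g_i b_i, and the internal variables recur as
#   h_i^{n+1} = e_i h_i^n + g_i b_i D (eps^{n+1} - eps^n).
# Integrated against B^T this is carried exactly as nodal force vectors
# Hvec_i with Hvec_i <- e_i Hvec_i + g_i b_i K0 (u^{n+1} - u^n).
#
# Unknown ordering: all u dofs (u_r, u_z interleaved per node), then p.
# Units: mm / s / N; moduli converted from kPa to N/mm^2; loads reported in mN.

gauss3 <- list(x = c(-sqrt(3 / 5), 0, sqrt(3 / 5)), w = c(5, 8, 5) / 9)

# 1-D quadratic Lagrange shape values/derivatives at xi on nodes (-1, 0, 1)
lag2 <- function(xi) c(xi * (xi - 1) / 2, 1 - xi^2, xi * (xi + 1) / 2)
dlag2 <- function(xi) c(xi - 0.5, -2 * xi, xi + 0.5)

# Elasticity matrix (N/mm^2) for strain vector (e_rr, e_zz, e_tt, gamma_rz)
elastic_D <- function(E_kPa, nu) {
  E <- E_kPa * 1e-3
  G <- E / (2 * (1 + nu)); lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  D <- diag(c(lam + 2 * G, lam + 2 * G, lam + 2 * G, G))
  D[1:3, 1:3][upper.tri(diag(3)) | lower.tri(diag(3))] <- lam
  D
}

# B matrix (4 x 18) at local point (xi, eta) of a rectangular element
# [r0,r1]x[z0,z1]; returns list(B, r) with r the physical radius.
axi_B <- function(xi, eta, r0, r1, z0, z1) {
  a <- (r1 - r0) / 2; b <- (z1 - z0) / 2
  r <- (r0 + r1) / 2 + a * xi
  lx <- lag2(xi); le <- lag2(eta); dlx <- dlag2(xi); dle <- dlag2(eta)
  N <- as.vector(outer(lx, le))          # length 9, order a + 3(b-1)
  dNdr <- as.vector(outer(dlx, le)) / a
  dNdz <- as.vector(outer(lx, dle)) / b
  B <- matrix(0, 4, 18)
  ir <- seq(1, 18, 2); iz <- seq(2, 18, 2)
  B[1, ir] <- dNdr
  B[2, iz] <- dNdz
  B[3, ir] <- N / r
  B[4, ir] <- dNdz
  B[4, iz] <- dNdr
  list(B = B, r = r, N = N)
}

# Assemble the constant operators: K0 (2Nu x 2Nu, instantaneous elastic),
# Q (2Nu x Np, coupling), H (Np x Np, Darcy), plus a block evaluator for
# element-level strain sampling.
fe_operators <- function(mesh, material) {
  D <- elastic_D(material$E, material$nu)
  kappa <- material$k / .gamma_w
  m <- c(1, 1, 1, 0)
  nu_dof <- 2L * mesh$n_unodes
  nel <- mesh$n_elem
  Ki <- Kj <- Kv <- vector("list", nel)
  Qi <- Qj <- Qv <- vector("list", nel)
  Hi <- Hj <- Hv <- vector("list", nel)
  e <- 0L
  for (ez in seq_len(mesh$nz)) for (er in seq_len(mesh$nr)) {
    e <- e + 1L
    r0 <- mesh$rb[er]; r1 <- mesh$rb[er + 1]
    z0 <- mesh$zb[ez]; z1 <- mesh$zb[ez + 1]
    a <- (r1 - r0) / 2; b <- (z1 - z0) / 2
    Ke <- matrix(0, 18, 18); Qe <- matrix(0, 18, 4); He <- matrix(0, 4, 4)
    for (q2 in 1:3) for (q1 in 1:3) {
      xi <- gauss3$x[q1]; eta <- gauss3$x[q2]
      w <- gauss3$w[q1] * gauss3$w[q2] * a * b
      bb <- axi_B(xi, eta, r0, r1, z0, z1)
      wr <- w * 2 * pi * bb$r
      Ke <- Ke + wr * crossprod(bb$B, D %*% bb$B)
      # bilinear pressure shapes and gradients
      Np <- c((1 - xi) * (1 - eta), (1 + xi) * (1 - eta),
              (1 - xi) * (1 + eta), (1 + xi) * (1 + eta)) / 4
      dNpdr <- c(-(1 - eta), (1 - eta), -(1 + eta), (1 + eta)) / 4 / a
      dNpdz <- c(-(1 - xi), -(1 + xi), (1 - xi), (1 + xi)) / 4 / b
      Qe <- Qe + wr * tcrossprod(crossprod(bb$B, m), Np)
      He <- He + wr * kappa * (tcrossprod(dNpdr) + tcrossprod(dNpdz))
    }
    un <- elem_unodes(mesh, er, ez)
    ud <- as.vector(rbind(2L * un - 1L, 2L * un))   # interleaved (r,z) dofs
    pn <- elem_pnodes(mesh, er, ez)
    Ki[[e]] <- rep(ud, times = 18); Kj[[e]] <- rep(ud, each = 18); Kv[[e]] <- as.vector(Ke)
    Qi[[e]] <- rep(ud, times = 4);  Qj[[e]] <- rep(pn, each = 18);  Qv[[e]] <- as.vector(Qe)
    Hi[[e]] <- rep(pn, times = 4);  Hj[[e]] <- rep(pn, each = 4);   Hv[[e]] <- as.vector(He)
  }
  K0 <- Matrix::sparseMatrix(i = unlist(Ki), j = unlist(Kj), x = unlist(Kv),
                             dims = c(nu_dof, nu_dof))
  Q  <- Matrix::sparseMatrix(i = unlist(Qi), j = unlist(Qj), x = unlist(Qv),
                             dims = c(nu_dof, mesh$n_pnodes))
  H  <- Matrix::sparseMatrix(i = unlist(Hi), j = unlist(Hj), x = unlist(Hv),
                             dims = c(mesh$n_pnodes, mesh$n_pnodes))
  list(K0 = K0, Q = Q, H = H, D = D)
}

# Transient mixed solver core.  Arguments:
#   cu_dofs      constrained displacement dof indices (global, fixed set)
#   cu_vals(t)   their prescribed values at time t
#   p_fixed      constrained pressure node indices (p = 0), possibly empty
#   react_dofs   subset of cu_dofs at which reactions are accumulated (load)
#   f_ext        constant external u-load vector (length 2Nu) or NULL
# Returns times, U, P (matrices with one column per time), reaction sums and
# per-step boundary outflow (mm^3).
fe_march <- function(mesh, material, prony, times, cu_dofs, cu_vals,
                     p_fixed = integer(), react_dofs = integer(), f_ext = NULL) {
  ops <- fe_operators(mesh, material)
  nu_dof <- 2L * mesh$n_unodes; np <- mesh$n_pnodes; ndof <- nu_dof + np
  nt <- length(times)
  stopifnot(nt >= 2, all(diff(times) > 0))
  g <- prony$g; tau <- prony$tau
  g_inf <- 1 - sum(g)
  if (is.null(f_ext)) f_ext <- numeric(nu_dof)

  idx_c <- c(cu_dofs, nu_dof + p_fixed)
  idx_f <- setdiff(seq_len(ndof), idx_c)

  U <- matrix(0, nu_dof, nt); P <- matrix(0, np, nt)
  reaction <- numeric(nt); outflow_step <- numeric(nt)
  Hvec <- replicate(length(g), numeric(nu_dof), simplify = FALSE)
  u_old <- numeric(nu_dof); Ku_old <- numeric(nu_dof)
  last_dt <- NA_real_; Aff <- NULL; Afc <- NULL; A <- NULL; lu <- NULL

  for (n in 2:nt) {
    dt <- times[n] - times[n - 1]
    ei <- exp(-dt / tau)
    bi <- if (length(g)) (tau / dt) * (1 - ei) else numeric()
    gam <- g_inf + sum(g * bi)
    if (is.na(last_dt) || abs(dt - last_dt) > 1e-12 * dt) {
      A <- rbind(cbind(gam * ops$K0, -ops$Q),
                 cbind(-Matrix::t(ops$Q), -dt * ops$H))
      Aff <- A[idx_f, idx_f, drop = FALSE]
      Afc <- A[idx_f, idx_c, drop = FALSE]
      lu <- Matrix::lu(Aff)
      last_dt <- dt
    }
    rhs_u <- f_ext + (sum(g * bi)) * Ku_old
    if (length(g)) for (i in seq_along(g)) rhs_u <- rhs_u - ei[i] * Hvec[[i]]
    rhs_p <- as.numeric(-Matrix::crossprod(ops$Q, u_old))
    rhs <- c(rhs_u, rhs_p)

    x <- numeric(ndof)
    x[cu_dofs] <- cu_vals(times[n])
    xf <- tryCatch(
      as.numeric(Matrix::solve(lu, rhs[idx_f] - as.numeric(Afc %*% x[idx_c]))),
      error = function(e2)
        stop(sprintf("linear solve failed at t = %g s: %s", times[n], conditionMessage(e2))))
    if (any(!is.finite(xf)))
      stop(sprintf("step did not converge at t = %g s (non-finite solution)", times[n]))
    x[idx_f] <- xf
    u_new <- x[seq_len(nu_dof)]; p_new <- x[nu_dof + seq_len(np)]

    resid <- as.numeric(A %*% x) - rhs
    if (length(react_dofs)) reaction[n] <- sum(resid[react_dofs])
    if (length(p_fixed)) outflow_step[n] <- sum(resid[nu_dof + p_fixed])

    Ku_new <- as.numeric(ops$K0 %*% u_new)
    if (length(g)) for (i in seq_along(g))
      Hvec[[i]] <- ei[i] * Hvec[[i]] + g[i] * bi[i] * (Ku_new - Ku_old)
    u_old <- u_new; Ku_old <- Ku_new
    U[, n] <- u_new; P[, n] <- p_new
  }
  list(times = times, U = U, P = P * 1e3,    # pressure N/mm^2 -> kPa
       reaction_N = reaction, outflow_step = outflow_step)
}

# Times vector from a dt schedule: data.frame(duration, dt) segments.
schedule_times <- function(dt_schedule) {
  stopifnot(all(dt_schedule$dt > 0), all(dt_schedule$duration > 0))
  t <- 0; out <- 0
  for (i in seq_len(nrow(dt_schedule))) {
    seg <- seq(t, t + dt_schedule$duration[i], by = dt_schedule$dt[i])[-1]
    if (!length(seg) || max(seg) < t + dt_schedule$duration[i] - 1e-9)
      seg <- c(seg, t + dt_schedule$duration[i])
    out <- c(out, seg); t <- t + dt_schedule$duration[i]
  }
  out
}

#' Default time-step schedule for a ramp-and-hold run
#'
#' Dense uniform steps during the ramp (at least 20), then geometrically
#' growing steps through the hold, backward Euler throughout.
#'
#' @param loading a [ramp_hold_loading()].
#' @param n_ramp steps during the ramp (>= 20 enforced).
#' @param n_hold steps during the hold.
#' @param growth geometric growth factor of hold steps.
#' @return Numeric vector of times starting at 0.
#' @export
dc_time_grid <- function(loading, n_ramp = 20, n_hold = 25, growth = 1.18) {
  n_ramp <- max(n_ramp, 20)
  tr <- seq(0, loading$t_ramp, length.out = n_ramp + 1)
  if (loading$t_hold <= 0) return(tr)
  raw <- growth^(seq_len(n_hold)) - 1
  th <- loading$t_ramp + loading$t_hold * raw / max(raw)
  c(tr, th)
}

#' Configuration of a craniectomy simulation
#'
#' @param geometry a [craniectomy_geometry()].
#' @param material a [poroelastic_params()].
#' @param prony a [prony_series()] (empty spectrum for a purely poro-elastic
#'   solid).
#' @param loading a [ramp_hold_loading()] for the platen.
#' @param pore_bc `"permeable"` (p = 0 on outer wall, bottom and the free top
#'   surface inside the opening; the platen contact itself is always
#'   impermeable) or `"impermeable"` (no-flux everywhere).
#' @param mesh_refinement list with `fine`, `far` element sizes, mm.
#' @param times explicit time grid, or NULL for [dc_time_grid()] defaults.
#' @param equal_order if TRUE, warns that equal-order interpolation is
#'   inf-sup unstable; the solver always uses the Taylor-Hood pair.
#' @return Object of class `dc_config`.
#' @export
dc_config <- function(geometry, material, prony = prony_series(), loading,
                      pore_bc = c("permeable", "impermeable"),
                      mesh_refinement = list(fine = 1.5, far = 6),
                      times = NULL, equal_order = FALSE) {
  pore_bc <- match.arg(pore_bc)
  stopifnot(inherits(geometry, "craniectomy_geometry"),
            inherits(material, "poroelastic_params"),
            inherits(prony, "prony_series"),
            inherits(loading, "ramp_hold_loading"))
  if (isTRUE(equal_order))
    warning("equal-order u/p interpolation violates the inf-sup condition; ",
            "using the stable biquadratic/bilinear (Taylor-Hood) pair instead")
  structure(list(geometry = geometry, material = material, prony = prony,
                 loading = loading, pore_bc = pore_bc,
                 mesh_refinement = mesh_refinement, times = times),
            class = "dc_config")
}

#' @export
print.dc_config <- function(x, ...) {
  cat("Craniectomy simulation configuration\n")
  print(x$geometry)
  cat(sprintf("  material: E = %g kPa, nu = %g, k = %g mm/s; %d Prony term(s)\n",
              x$material$E, x$material$nu, x$material$k, length(x$prony$g)))
  cat(sprintf("  loading: %g mm over %g s, hold %g s; pore BC %s\n",
              x$loading$u_max, x$loading$t_ramp, x$loading$t_hold, x$pore_bc))
  invisible(x)
}

# Vertical offset of a quarter-round (fillet) platen edge above the flat
# platen face, for radii in the transition band [a_c, a_c + R_f]: zero on the
# flat face (r >= a_c + R_f), rising to R_f at the opening edge r = a_c.
# A point of the top surface at radius r is displaced by max(u_p - delta, 0):
# the fillet relieves the displacement near the edge, and the contact radius
# grows as the platen descends, which is how a rounded rigid edge loads the
# surface when lift-off is neglected.
fillet_offset <- function(r, a_c, R_f) {
  if (R_f <= 0) return(ifelse(r >= a_c - 1e-9, 0, Inf))
  ifelse(r >= a_c + R_f, 0,
         ifelse(r < a_c, Inf,
                R_f - sqrt(pmax(R_f^2 - (a_c + R_f - r)^2, 0))))
}

#' Run an axisymmetric poro-viscoelastic craniectomy simulation
#'
#' Solves the mixed displacement-pressure Biot system with Prony solid
#' relaxation on the idealised craniectomy domain.  Boundary conditions:
#' `u_r = 0` on the axis and the outer wall, `u_z = 0` on the bottom; on the
#' top surface, nodes under the platen follow the prescribed ramp-and-hold
#' displacement with free radial slip.  Across the fillet band
#' `[a_c, a_c + R_f]` the displacement is relieved by the quarter-round edge
#' profile, `u_z = -max(u_p(t) - delta(r), 0)`, so the contact radius grows
#' as the platen descends; surface nodes the platen never reaches, and the
#' opening `r < a_c`, are traction-free.  Pore pressure is fixed to zero on permeable external
#' boundaries (never under the platen); the platen load is the sum of the
#' discrete reaction forces at the prescribed vertical dofs.
#'
#' @param config a [dc_config()].
#' @return Object of class `dc_history`: `times` (s), `platen_load`
#'   (mN, compression positive), nodal fields `U` (mm) and `P` (kPa),
#'   per-element centre strain array, `cumulative_outflow` (mm^3), the mesh
#'   and config.
#' @export
run_dc_simulation <- function(config) {
  stopifnot(inherits(config, "dc_config"))
  geo <- config$geometry
  mesh <- build_dc_mesh(geo, config$mesh_refinement)
  times <- if (is.null(config$times)) dc_time_grid(config$loading) else config$times
  nru <- length(mesh$ru); nzu <- length(mesh$zu)

  # displacement constraints
  axis_nodes  <- unode_index(mesh, 1L, seq_len(nzu))
  wall_nodes  <- unode_index(mesh, nru, seq_len(nzu))
  bot_nodes   <- unode_index(mesh, seq_len(nru), 1L)
  load <- config$loading
  delta_all <- fillet_offset(mesh$ru, geo$a_c, geo$R_f)
  # constrain only top nodes the platen actually reaches by peak displacement
  top_i <- which(delta_all < load$u_max - 1e-9)
  platen_nodes <- unode_index(mesh, top_i, nzu)
  delta <- delta_all[top_i]
  # short fixed-width cosine taper at the opening edge: removes the
  # displacement discontinuity a small fillet leaves at r = a_c (a flat-punch
  # singularity whose discrete reaction would not converge with refinement)
  w <- min(1, max(geo$a_c, 1e-6))
  sreg <- if (geo$a_c > 0) {
    s <- pmin(pmax((mesh$ru[top_i] - geo$a_c) / w, 0), 1)
    0.5 * (1 - cos(pi * s))
  } else rep(1, length(top_i))
  cu_dofs <- c(2L * axis_nodes - 1L, 2L * wall_nodes - 1L,
               2L * bot_nodes, 2L * platen_nodes)
  uplat <- function(t) load$u_max * min(t / load$t_ramp, 1)
  cu_vals <- function(t) c(numeric(length(axis_nodes) + length(wall_nodes) +
                                     length(bot_nodes)),
                           -pmax(uplat(t) - delta, 0) * sreg)

  # pressure constraints (p = 0 on permeable boundaries)
  p_fixed <- integer()
  if (config$pore_bc == "permeable") {
    nrp <- length(mesh$rb); nzp <- length(mesh$zb)
    wall_p <- pnode_index(mesh, nrp, seq_len(nzp))
    bot_p  <- pnode_index(mesh, seq_len(nrp), 1L)
    free_i <- which(fillet_offset(mesh$rb, geo$a_c, geo$R_f) >= load$u_max - 1e-9)
    top_free_p <- if (length(free_i)) pnode_index(mesh, free_i, nzp) else integer()
    p_fixed <- sort(unique(c(wall_p, bot_p, top_free_p)))
  }

  sol <- fe_march(mesh, config$material, config$prony, times,
                  cu_dofs, cu_vals, p_fixed,
                  react_dofs = 2L * platen_nodes)
  strain <- element_centre_strains(mesh, sol$U)
  structure(list(times = sol$times,
                 platen_load = -sol$reaction_N * 1e3,   # N -> mN, compression +
                 U = sol$U, P = sol$P,
                 strain = strain,
                 cumulative_outflow = cumsum(sol$outflow_step),
                 pore_bc = config$pore_bc,
                 mesh = mesh, config = config),
            class = c("dc_history", "fe_history"))
}

#' @export
print.dc_history <- function(x, ...) {
  cat(sprintf("Craniectomy simulation: %d time steps to t = %g s\n",
              length(x$times) - 1, max(x$times)))
  cat(sprintf("  peak platen load %.4g mN; final load %.4g mN\n",
              max(x$platen_load), x$platen_load[length(x$times)]))
  if (x$pore_bc == "permeable")
    cat(sprintf("  cumulative boundary outflow %.4g mm^3\n",
                x$cumulative_outflow[length(x$times)]))
  invisible(x)
}

#' @export
plot.dc_history <- function(x, ...) {
  graphics::plot(x$times, x$platen_load, type = "l", lwd = 2,
                 xlab = "time (s)", ylab = "platen load (mN)",
                 main = "Load relaxation", ...)
  invisible(x)
}

# Strain (e_rr, e_zz, e_tt, e_rz tensor shear) at each element centre for
# every stored time; returns array (n_elem x 4 x nt).
element_centre_strains <- function(mesh, U) {
  nel <- mesh$n_elem; nt <- ncol(U)
  Bi <- Bj <- Bv <- vector("list", nel)
  e <- 0L
  for (ez in seq_len(mesh$nz)) for (er in seq_len(mesh$nr)) {
    e <- e + 1L
    bb <- axi_B(0, 0, mesh$rb[er], mesh$rb[er + 1], mesh$zb[ez], mesh$zb[ez + 1])
    un <- elem_unodes(mesh, er, ez)
    ud <- as.vector(rbind(2L * un - 1L, 2L * un))
    rows <- (e - 1L) * 4L + 1:4
    Bi[[e]] <- rep(rows, times = 18)
    Bj[[e]] <- rep(ud, each = 4)
    Bv[[e]] <- as.vector(bb$B)
  }
  Bc <- Matrix::sparseMatrix(i = unlist(Bi), j = unlist(Bj), x = unlist(Bv),
                             dims = c(4L * nel, nrow(U)))
  S <- as.matrix(Bc %*% U)
  arr <- array(S, dim = c(4, nel, nt))
  arr <- aperm(arr, c(2, 1, 3))
  arr[, 4, ] <- arr[, 4, ] / 2       # engineering gamma_rz -> tensor e_rz
  dimnames(arr) <- list(NULL, c("e_rr", "e_zz", "e_tt", "e_rz"), NULL)
  arr
}

# Element-centre coordinates, n_elem x 2 (r, z), same ordering as strains.
element_centres <- function(mesh) {
  rc <- (mesh$rb[-1] + mesh$rb[-length(mesh$rb)]) / 2
  zc <- (mesh$zb[-1] + mesh$zb[-length(mesh$zb)]) / 2
  cbind(r = rep(rc, times = mesh$nz), z = rep(zc, each = mesh$nr))
}

#' Cumulative boundary fluid outflow of a simulation
#'
#' Integrates the discrete Darcy flux across the pressure-constrained
#' (permeable) boundary over time.  For an impermeable run this is
#' identically zero and a notice is given.
#'
#' @param history a `dc_history` or `terzaghi_column` result.
#' @return data.frame with `time_s` and `outflow_mm3` (non-decreasing for a
#'   permeable run).
#' @export
boundary_fluid_volume <- function(history) {
  stopifnot(inherits(history, "fe_history"))
  if (identical(history$pore_bc, "impermeable")) {
    message("impermeable boundaries: no fluid outflow")
    return(data.frame(time_s = history$times,
                      outflow_mm3 = numeric(length(history$times))))
  }
  data.frame(time_s = history$times, outflow_mm3 = history$cumulative_outflow)
}

#' Sample the strain field along an axis-aligned line
#'
#' Evaluates the finite-element strain (from the biquadratic displacement
#' field) at `n` points on a segment parallel to one of the axes.
#'
#' @param history a `dc_history`.
#' @param line list with `from = c(r, z)` and `to = c(r, z)`, mm; must be
#'   axis-aligned and inside the domain.
#' @param time physical time, s; the nearest stored step is used.
#' @param n number of sample points.
#' @return data.frame with arc-length `s`, coordinates `r`, `z`, and tensor
#'   strain components `e_rr`, `e_zz`, `e_tt`, `e_rz`.
#' @export
sample_strain <- function(history, line, time, n = 100) {
  stopifnot(inherits(history, "fe_history"))
  mesh <- history$mesh
  from <- line$from; to <- line$to
  if (abs(from[1] - to[1]) > 1e-12 && abs(from[2] - to[2]) > 1e-12)
    stop("sampling line must be axis-aligned")
  R <- max(mesh$rb); H <- max(mesh$zb)
  if (any(c(from, to) < -1e-9) || from[1] > R + 1e-9 || to[1] > R + 1e-9 ||
      from[2] > H + 1e-9 || to[2] > H + 1e-9)
    stop("sampling line lies outside the domain")
  if (time < min(history$times) - 1e-9 || time > max(history$times) + 1e-9)
    stop("requested time outside the solution history")
  it <- which.min(abs(history$times - time))
  u <- history$U[, it]
  tt <- seq(0, 1, length.out = n)
  pr <- from[1] + tt * (to[1] - from[1])
  pz <- from[2] + tt * (to[2] - from[2])
  eps <- 1e-9
  er_idx <- pmin(pmax(findInterval(pmin(pr, R - eps), mesh$rb,
                                   rightmost.closed = TRUE), 1L), mesh$nr)
  ez_idx <- pmin(pmax(findInterval(pmin(pz, H - eps), mesh$zb,
                                   rightmost.closed = TRUE), 1L), mesh$nz)
  out <- matrix(0, n, 4)
  for (i in seq_len(n)) {
    er <- er_idx[i]; ez <- ez_idx[i]
    r0 <- mesh$rb[er]; r1 <- mesh$rb[er + 1]
    z0 <- mesh$zb[ez]; z1 <- mesh$zb[ez + 1]
    xi <- 2 * (pr[i] - (r0 + r1) / 2) / (r1 - r0)
    eta <- 2 * (pz[i] - (z0 + z1) / 2) / (z1 - z0)
    # on the axis the hoop term u_r / r is evaluated just off r = 0
    if (pr[i] < 1e-9) xi <- xi + 1e-6
    bb <- axi_B(xi, eta, r0, r1, z0, z1)
    un <- elem_unodes(mesh, er, ez)
    ud <- as.vector(rbind(2L * un - 1L, 2L * un))
    out[i, ] <- as.numeric(bb$B %*% u[ud])
  }
  out[, 4] <- out[, 4] / 2
  data.frame(s = tt * sqrt(sum((to - from)^2)), r = pr, z = pz,
             e_rr = out[, 1], e_zz = out[, 2], e_tt = out[, 3], e_rz = out[, 4])
}

#' One-dimensional Terzaghi consolidation column (verification harness)
#'
#' Solves a laterally confined, top-drained column with the same axisymmetric
#' assembly as [run_dc_simulation()]: `u_r = 0` everywhere, `u_z = 0` at the
#' bottom, a constant vertical traction on the top face applied from the
#' first step, and `p = 0` at the top only.  With the Prony spectrum empty
#' this is the classical Terzaghi problem, whose settlement history obeys
#' `s(t) = s_inf U(c t / h^2)`.
#'
#' @param material a [poroelastic_params()].
#' @param column_height column height (drainage path), mm.
#' @param applied_load total compressive load on the column, N.
#' @param times time grid, s (first entry 0).
#' @param radius column radius, mm.
#' @param nz,nr element counts.
#' @param prony a [prony_series()]; defaults to empty (pure poro-elastic).
#' @return Object of class `terzaghi_column`: `times`, `settlement` (mm,
#'   positive down), `cumulative_outflow`, mesh and fields.
#' @export
run_terzaghi_column <- function(material, column_height, applied_load, times,
                                radius = 5, nz = 30, nr = 2,
                                prony = prony_series()) {
  stopifnot(inherits(material, "poroelastic_params"), applied_load > 0)
  geo <- craniectomy_geometry(radius, column_height, a_c = 0, R_f = 0)
  mesh <- build_dc_mesh(geo, list(fine = min(radius / nr, column_height / nz),
                                  far = max(radius / nr, column_height / nz)))
  # exact uniform grid for the column
  mesh <- local({
    rb <- seq(0, radius, length.out = nr + 1)
    zb <- seq(0, column_height, length.out = nz + 1)
    mid <- function(b) { v <- numeric(2 * length(b) - 1)
      v[seq(1, length(v), 2)] <- b
      v[seq(2, length(v), 2)] <- (b[-1] + b[-length(b)]) / 2; v }
    structure(list(rb = rb, zb = zb, nr = nr, nz = nz,
                   ru = mid(rb), zu = mid(zb),
                   n_unodes = (2 * nr + 1) * (2 * nz + 1),
                   n_pnodes = (nr + 1) * (nz + 1),
                   n_elem = nr * nz, geometry = geo,
                   refinement = list(fine = radius / nr, far = column_height / nz)),
              class = "aximesh")
  })
  nru <- length(mesh$ru); nzu <- length(mesh$zu)
  all_nodes <- seq_len(mesh$n_unodes)
  bot_nodes <- unode_index(mesh, seq_len(nru), 1L)
  cu_dofs <- c(2L * all_nodes - 1L, 2L * bot_nodes)     # u_r = 0 everywhere
  cu_vals <- function(t) numeric(length(cu_dofs))
  # drainage at the top surface only
  p_fixed <- pnode_index(mesh, seq_len(length(mesh$rb)), length(mesh$zb))
  # consistent nodal loads for uniform traction -P e_z on the top edge
  Pz <- applied_load / (pi * radius^2) * 1e0             # N/mm^2
  f_ext <- numeric(2L * mesh$n_unodes)
  for (er in seq_len(mesh$nr)) {
    r0 <- mesh$rb[er]; r1 <- mesh$rb[er + 1]; a <- (r1 - r0) / 2
    un <- elem_unodes(mesh, er, mesh$nz)[7:9]            # top-edge nodes of element
    for (q in 1:3) {
      xi <- gauss3$x[q]; w <- gauss3$w[q] * a
      r <- (r0 + r1) / 2 + a * xi
      N <- lag2(xi)
      f_ext[2L * un] <- f_ext[2L * un] - Pz * N * 2 * pi * r * w
    }
  }
  sol <- fe_march(mesh, material, prony, times, cu_dofs, cu_vals, p_fixed,
                  react_dofs = integer(), f_ext = f_ext)
  top_mid <- unode_index(mesh, 1L, nzu)
  structure(list(times = sol$times,
                 settlement = -sol$U[2L * top_mid, ],
                 U = sol$U, P = sol$P,
                 cumulative_outflow = cumsum(sol$outflow_step),
                 pore_bc = "permeable", applied_load = applied_load,
                 radius = radius, column_height = column_height,
                 mesh = mesh),
            class = c("terzaghi_column", "fe_history"))
}

#' @export
print.terzaghi_column <- function(x, ...) {
  cat(sprintf("Terzaghi column: h = %g mm, load %g N; final settlement %.4g mm\n",
              x$column_height, x$applied_load, x$settlement[length(x$times)]))
  invisible(x)
}

#' Write a load history to CSV
#'
#' @param history a `dc_history`.
#' @param path output CSV (`time_s`, `load_mN`).
#' @return `path`, invisibly.
#' @export
write_load_csv <- function(history, path) {
  stopifnot(inherits(history, "dc_history"))
  utils::write.csv(data.frame(time_s = history$times, load_mN = history$platen_load),
                   path, row.names = FALSE)
  invisible(path)
}
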