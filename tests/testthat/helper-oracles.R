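# Independent oracles used across the suite.  These deliberately re-derive
# quantities with brute-force or closed-form routes separate from the
# package implementation.

# Brute-force Terzaghi series with a very large number of terms.
terzaghi_brute <- function(T_, n = 20000) {
  m <- 0:(n - 1)
  M <- pi * (2 * m + 1) / 2
  vapply(T_, function(Ti) 1 - sum((2 / M^2) * exp(-M^2 * Ti)), numeric(1))
}

# Brute-force circumcircle test: does any other point lie strictly inside
# the circumcircle of triangle (i, j, k)?
circumcircle_violated <- function(pts, tri, tol = 1e-9) {
  for (r in seq_len(nrow(tri))) {
    v <- tri[r, ]
    ax <- pts[v[1], 1]; ay <- pts[v[1], 2]
    bx <- pts[v[2], 1]; by <- pts[v[2], 2]
    cx <- pts[v[3], 1]; cy <- pts[v[3], 2]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(d) < 1e-12) next
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
    rad <- sqrt((ax - ux)^2 + (ay - uy)^2)
    others <- setdiff(seq_len(nrow(pts)), v)
    dd <- sqrt((pts[others, 1] - ux)^2 + (pts[others, 2] - uy)^2)
    if (any(dd < rad - tol)) return(TRUE)
  }
  FALSE
}

# Small, fast column solve used by several FE tests.
quick_column <- function(k = 1e-3, h = 20, load = 2, n_steps = 60, nz = 30) {
  mat <- poroelastic_params(E = 20, nu = 0.3, k = k)
  cc <- consolidation_coefficient(mat)
  tend <- 2.5 * h^2 / cc
  times <- c(0, exp(seq(log(0.02), log(tend), length.out = n_steps)))
  list(material = mat, c = cc,
       col = run_terzaghi_column(mat, h, load, times, nz = nz),
       times = times, h = h)
}

# Tiny fast craniectomy configuration for unit tests (not the demonstration
# conditions; just exercises the machinery cheaply).
quick_dc_config <- function(...) {
  dm <- dc_demo_material()
  dc_config(craniectomy_geometry(40, 25, a_c = 12, R_f = 3),
            dm$material, dm$prony,
            ramp_hold_loading(u_max = 2, t_ramp = 2, t_hold = 60),
            mesh_refinement = list(fine = 2, far = 6), ...)
}
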