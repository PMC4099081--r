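# Closed-form poro-viscoelastic constitutive functions.
#
# Unit system used throughout the package: mm / s / N.  Moduli are entered in
# kPa and converted internally to N/mm^2 (1 kPa = 1e-3 N/mm^2), so that
# kPa * mm^2 = mN.  Hydraulic conductivity k is in mm/s; the Darcy mobility is
# kappa = k / gamma_w with gamma_w = 9.81e-6 N/mm^3 (unit weight of water).

#' Unit weight of water, N/mm^3
#' @keywords internal
.gamma_w <- 9.81e-6

#' Prony relaxation spectrum
#'
#' A dimensionless sum-of-exponentials relaxation spectrum applied equally to
#' the shear and bulk moduli of the solid skeleton (the `g_i = k_i`
#' assumption), so a single spectrum scales the whole elastic stiffness.
#'
#' @param g numeric vector of dimensionless relaxation fractions, each in
#'   (0,1), with `sum(g) < 1`.
#' @param tau numeric vector of time constants in seconds, all positive,
#'   same length as `g`.
#' @return An object of class `prony_series` with terms sorted by ascending
#'   `tau`.
#' @examples
#' prony_series(g = c(0.2, 0.1), tau = c(1, 50))
#' @export
prony_series <- function(g = numeric(), tau = numeric()) {
  g <- as.numeric(g); tau <- as.numeric(tau)
  if (length(g) != length(tau))
    stop("'g' and 'tau' must have the same length")
  if (length(g)) {
    if (any(!is.finite(g)) || any(g <= 0) || any(g >= 1))
      stop("all relaxation fractions g_i must lie in (0, 1)")
    if (sum(g) >= 1)
      stop("sum of relaxation fractions must be < 1 (long-term modulus > 0)")
    if (any(!is.finite(tau)) || any(tau <= 0))
      stop("all time constants tau_i must be positive")
    ord <- order(tau)
    g <- g[ord]; tau <- tau[ord]
  }
  structure(list(g = g, tau = tau), class = "prony_series")
}

#' @export
print.prony_series <- function(x, ...) {
  n <- length(x$g)
  cat("Prony relaxation spectrum (", n, " term", if (n != 1) "s", ")\n", sep = "")
  if (n) {
    print(data.frame(g = x$g, tau_s = x$tau), row.names = FALSE)
    cat("long-term fraction g_inf =", format(1 - sum(x$g)), "\n")
  } else cat("  (empty: no relaxation, purely elastic solid)\n")
  invisible(x)
}

#' Poro-elastic material parameters
#'
#' Instantaneous drained elastic constants and hydraulic conductivity of a
#' fluid-saturated solid with incompressible constituents.
#'
#' @param E instantaneous Young's modulus, kPa.
#' @param nu drained Poisson's ratio (long-time, fluid equilibrated).
#' @param k hydraulic conductivity, mm/s.
#' @param nu_u undrained Poisson's ratio; defaults to 0.5 (incompressible
#'   constituents).
#' @return An object of class `poroelastic_params` with derived shear modulus
#'   `G` (kPa).
#' @examples
#' poroelastic_params(E = 20, nu = 0.3, k = 1e-4)
#' @export
poroelastic_params <- function(E, nu, k, nu_u = 0.5) {
  stopifnot(is.finite(E), E > 0, is.finite(k), k > 0, is.finite(nu))
  if (!(nu > -1 && nu < nu_u && nu_u <= 0.5))
    stop("need -1 < nu < nu_u <= 0.5")
  structure(list(E = E, nu = nu, k = k, nu_u = nu_u, G = E / (2 * (1 + nu))),
            class = "poroelastic_params")
}

#' @export
print.poroelastic_params <- function(x, ...) {
  cat("Poro-elastic parameters:\n")
  cat(sprintf("  E    = %g kPa (instantaneous Young's modulus)\n", x$E))
  cat(sprintf("  G    = %g kPa (shear modulus)\n", x$G))
  cat(sprintf("  nu   = %g (drained), nu_u = %g (undrained)\n", x$nu, x$nu_u))
  cat(sprintf("  k    = %g mm/s (hydraulic conductivity)\n", x$k))
  if (x$nu < 0.5)
    cat(sprintf("  c    = %g mm^2/s (consolidation coefficient)\n",
                consolidation_coefficient(x)))
  invisible(x)
}

#' Cylindrical sample geometry
#'
#' @param height_h sample height, mm.
#' @param diameter_d sample diameter, mm.
#' @return Object of class `sample_geometry`.
#' @export
sample_geometry <- function(height_h, diameter_d) {
  stopifnot(is.finite(height_h), height_h > 0, is.finite(diameter_d), diameter_d > 0)
  structure(list(height_h = height_h, diameter_d = diameter_d),
            class = "sample_geometry")
}

#' Ramp-and-hold loading programme
#'
#' Displacement-controlled loading: a linear ramp to `u_max` over `t_ramp`
#' seconds followed by a hold of `t_hold` seconds.
#'
#' @param u_max peak platen displacement, mm (> 0).
#' @param t_ramp ramp duration, s (> 0).
#' @param t_hold hold duration, s (>= 0).
#' @return Object of class `ramp_hold_loading`.
#' @export
ramp_hold_loading <- function(u_max, t_ramp, t_hold) {
  stopifnot(is.finite(u_max), u_max > 0, is.finite(t_ramp), t_ramp > 0,
            is.finite(t_hold), t_hold >= 0)
  structure(list(u_max = u_max, t_ramp = t_ramp, t_hold = t_hold),
            class = "ramp_hold_loading")
}

#' Dimensionless relaxation function
#'
#' Evaluates `g_R(t) = 1 - sum_i g_i (1 - exp(-t / tau_i))`, the normalised
#' relaxation modulus of a Prony spectrum.  `g_R(0) = 1` and
#' `g_R(Inf) = 1 - sum(g)`.
#'
#' @param prony a [prony_series()].
#' @param t time(s) in seconds, all >= 0 (vectorised).
#' @return Numeric vector of dimensionless moduli in `(1 - sum(g), 1]`.
#' @examples
#' relaxation_function(prony_series(0.5, 1), t = c(0, 1, Inf))
#' @export
relaxation_function <- function(prony, t) {
  stopifnot(inherits(prony, "prony_series"))
  if (any(t < 0, na.rm = TRUE) || any(is.na(t)))
    stop("time 't' must be non-negative")
  if (!length(prony$g)) return(rep(1, length(t)))
  decay <- vapply(seq_along(prony$g), function(i)
    prony$g[i] * (1 - exp(-t / prony$tau[i])), numeric(length(t)))
  1 - rowSums(matrix(decay, nrow = length(t)))
}

#' Ramp correction factor
#'
#' Correction for the finite rise time of a displacement-controlled test:
#' `R(tau, t_ramp) = (tau / t_ramp) * (exp(t_ramp / tau) - 1)`.  Tends to 1 as
#' the ramp becomes instantaneous, and always `>= 1`.
#'
#' @param tau relaxation time constant, s (> 0); vectorised.
#' @param t_ramp ramp duration, s (> 0).
#' @return Dimensionless correction factor(s).
#' @examples
#' ramp_correction(tau = 1, t_ramp = 1)  # e - 1
#' @export
ramp_correction <- function(tau, t_ramp) {
  if (any(!is.finite(tau)) || any(tau <= 0))
    stop("'tau' must be positive")
  if (!is.finite(t_ramp) || t_ramp <= 0)
    stop("'t_ramp' must be positive")
  x <- t_ramp / tau
  # expm1 keeps the instantaneous-ramp limit accurate for tiny t_ramp/tau
  expm1(x) / x
}

#' Force relaxation in ramp-and-hold unconfined compression
#'
#' Closed-form post-ramp force response of a cylindrical sample under
#' displacement-controlled unconfined compression, using a ramp-corrected
#' Prony series (Boltzmann hereditary integral with a linear ramp):
#' `F(t) = (pi d^2 / 4h) u_max * (C0 + sum_i C_i R_i exp(-(t - t_ramp)/tau_i))`
#' where `R_i = ramp_correction(tau_i, t_ramp)`.
#'
#' @param C0 long-term modulus, kPa.
#' @param C vector of Prony moduli, kPa.
#' @param tau vector of time constants, s (same length as `C`).
#' @param geom a [sample_geometry()].
#' @param load a [ramp_hold_loading()].
#' @param t evaluation times, s; all must be `>= t_ramp` (the model describes
#'   the hold phase only).
#' @return Force in mN (kPa mm^2), monotone non-increasing in `t`.
#' @examples
#' unconfined_force_relaxation(5, C = 5, tau = 10,
#'   geom = sample_geometry(10, 20),
#'   load = ramp_hold_loading(1, 0.001, 100), t = 0.001)
#' @export
unconfined_force_relaxation <- function(C0, C, tau, geom, load, t) {
  stopifnot(inherits(geom, "sample_geometry"), inherits(load, "ramp_hold_loading"),
            length(C) == length(tau), C0 > 0)
  if (any(t < load$t_ramp))
    stop("model is valid for the hold phase only: need t >= t_ramp")
  amp <- pi * geom$diameter_d^2 / (4 * geom$height_h) * load$u_max
  mod <- rep(C0, length(t))
  if (length(C)) {
    R <- ramp_correction(tau, load$t_ramp)
    for (i in seq_along(C))
      mod <- mod + C[i] * R[i] * exp(-(t - load$t_ramp) / tau[i])
  }
  amp * mod
}

#' Terzaghi degree of consolidation
#'
#' One-dimensional consolidation of a uniformly loaded, singly drained layer:
#' `U(T) = 1 - sum_m (2 / M_m^2) exp(-M_m^2 T)` with `M_m = pi (2m + 1) / 2`,
#' where `T = c t / h^2` is dimensionless time.
#'
#' @param T_ dimensionless time(s), >= 0 (vectorised).
#' @param n_terms number of series terms (default 200), ample for machine
#'   accuracy at `T_ >= 1e-4`; below that the exact early-time expansion
#'   `2 sqrt(T/pi)` is used (its finite-layer correction is `O(exp(-1/4T))`,
#'   far below double precision there).
#' @return Degree of consolidation in `[0, 1]`, strictly increasing in `T_`.
#' @examples
#' terzaghi_consolidation(0.197)  # ~ 0.5, the classical half-consolidation time
#' @export
terzaghi_consolidation <- function(T_, n_terms = 200) {
  stopifnot(n_terms >= 1)
  if (any(T_ < 0, na.rm = TRUE) || any(is.na(T_)))
    stop("dimensionless time must be non-negative")
  m <- 0:(n_terms - 1)
  M <- pi * (2 * m + 1) / 2
  U <- vapply(T_, function(Ti) {
    if (Ti < 1e-4) return(2 * sqrt(Ti / pi))
    1 - sum((2 / M^2) * exp(-M^2 * Ti))
  }, numeric(1))
  pmin(pmax(U, 0), 1)
}

#' Consolidation coefficient from poro-elastic parameters
#'
#' For incompressible constituents (`nu_u = 0.5`, Skempton B = 1) the
#' consolidation coefficient reduces to
#' `c = 2 kappa G (1 - nu) / (1 - 2 nu)` with `kappa = k / gamma_w`,
#' `gamma_w = 9.81e-6 N/mm^3`, and `G` in N/mm^2.
#'
#' @param params a [poroelastic_params()].
#' @return Consolidation coefficient `c` in mm^2/s.
#' @examples
#' consolidation_coefficient(poroelastic_params(E = 26, nu = 0.3, k = 1e-3))
#' @export
consolidation_coefficient <- function(params) {
  stopifnot(inherits(params, "poroelastic_params"))
  if (params$nu >= 0.5)
    stop("drained Poisson's ratio at the incompressibility limit (nu >= 0.5): ",
         "consolidation coefficient is singular")
  kappa <- params$k / .gamma_w               # mm^4 / (N s)
  G_Nmm2 <- params$G * 1e-3                  # kPa -> N/mm^2
  2 * kappa * G_Nmm2 * (1 - params$nu) / (1 - 2 * params$nu)
}

#' Invert the consolidation coefficient for hydraulic conductivity
#'
#' Given `c`, `G` and `nu`, recovers `k` from
#' `c = 2 (k / gamma_w) G (1 - nu) / (1 - 2 nu)`.
#'
#' @param c consolidation coefficient, mm^2/s.
#' @param G shear modulus, kPa.
#' @param nu drained Poisson's ratio (< 0.5).
#' @return Hydraulic conductivity, mm/s.
#' @export
conductivity_from_c <- function(c, G, nu) {
  stopifnot(c > 0, G > 0, nu < 0.5)
  c * .gamma_w * (1 - 2 * nu) / (2 * (G * 1e-3) * (1 - nu))
}
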