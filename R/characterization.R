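# Identification of PVE parameters from compression relaxation curves.
#
# The visco-elastic stage fits the ramp-corrected Prony force relaxation to an
# unconfined-compression hold phase; the poro-elastic stage fits the Terzaghi
# consolidation settlement to a confined-compression hold phase.  Both are
# nonlinear least squares (Levenberg-Marquardt via minpack.lm) with seeded
# multi-start initialisation, since Prony fitting is multi-modal.

#' Fit a ramp-corrected Prony series to an unconfined force-relaxation curve
#'
#' Minimises the sum of squared residuals between the hold-phase force record
#' and [unconfined_force_relaxation()] over `{C0, C_i, tau_i}`.  Parameters
#' are kept positive by optimising their logarithms.  `n_starts` restarts are
#' used, each with initial time constants log-spaced over `[0.1, 1000]` s and
#' randomly jittered; the best converged fit is returned with `tau` sorted
#' ascending.
#'
#' @param curve a [relaxation_curve()] with mode `"unconfined-force"`.
#' @param n_terms number of Prony terms (default 3).
#' @param seed integer seed controlling the multi-start jitter.
#' @param n_starts number of restarts (>= 5 recommended).
#' @return Object of class `prony_fit` with elements `C0`, `C`, `tau` (kPa /
#'   s), `E_inst = C0 + sum(C)`, `residual_rms` (mN), the data, and the
#'   converged objective.
#' @export
fit_unconfined <- function(curve, n_terms = 3, seed = 1L, n_starts = 7L) {
  stopifnot(inherits(curve, "relaxation_curve"))
  if (curve$mode != "unconfined-force")
    stop("fit_unconfined() needs an unconfined-force curve")
  load <- curve$loading
  stopifnot(inherits(load, "ramp_hold_loading"))
  keep <- curve$time >= load$t_ramp
  if (sum(keep) < 10) stop("no usable hold-phase samples (t >= t_ramp)")
  t <- curve$time[keep]; F_obs <- curve$value[keep]
  amp <- pi * curve$geom$diameter_d^2 / (4 * curve$geom$height_h) * load$u_max

  # log-parameterised model, kept finite wherever Levenberg-Marquardt roams:
  # parameters are clamped in log space and each Prony term is evaluated as a
  # single capped exponent exp(log C_i + log R_i - (t - t_r)/tau_i)
  model_force <- function(logpar) {
    lp <- pmin(pmax(logpar, -20), 20)
    C0 <- exp(lp[1]); tau <- exp(lp[(2 + n_terms):(1 + 2 * n_terms)])
    x <- load$t_ramp / tau
    logR <- ifelse(x > 25, x - log(x), log(expm1(x) / x))
    mod <- rep(C0, length(t))
    for (i in seq_len(n_terms))
      mod <- mod + exp(pmin(lp[1 + i] + logR[i] - (t - load$t_ramp) / tau[i], 50))
    amp * mod
  }

  plateau <- stats::median(utils::tail(F_obs, max(5L, length(F_obs) %/% 10)))
  peak <- max(F_obs)
  C0_init <- max(plateau / amp, 1e-6)
  Ctot_init <- max((peak - plateau) / amp, 1e-6)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))

  best <- NULL; best_ss <- Inf; n_ok <- 0L
  tau_base <- exp(seq(log(1), log(100), length.out = n_terms))
  for (s in seq_len(n_starts)) {
    # first start: deterministic log-spaced tau; later starts: log-uniform
    # draws over [0.1, 1000] s with jittered amplitudes
    if (s == 1) {
      tau0 <- tau_base
      amp_jit <- rep(1, n_terms + 1)
    } else {
      tau0 <- sort(10^stats::runif(n_terms, -1, 3))
      amp_jit <- exp(stats::rnorm(n_terms + 1, 0, 0.5))
    }
    start <- log(c(C0_init * amp_jit[1],
                   rep(Ctot_init / n_terms, n_terms) * amp_jit[-1],
                   tau0))
    # the tiny ridge on the Prony amplitudes resolves the degeneracy of
    # constant records (C_i with tau -> Inf vs C0); its bias on identifiable
    # fits is O(1e-9) relative
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start,
                         fn = function(lp) c(F_obs - model_force(lp),
                                             1e-3 * amp * exp(pmin(lp[2:(1 + n_terms)], 20))),
                         control = minpack.lm::nls.lm.control(maxiter = 400)),
      error = function(e) NULL)
    if (is.null(fit)) next
    n_ok <- n_ok + 1L
    ss <- sum(fit$fvec^2)
    if (ss < best_ss) { best_ss <- ss; best <- fit }
  }
  if (is.null(best))
    stop(sprintf("unconfined Prony fit failed to converge in any of %d restarts", n_starts))

  p <- exp(pmin(pmax(best$par, -20), 20))
  C0 <- p[1]; C <- p[2:(1 + n_terms)]; tau <- p[(2 + n_terms):(1 + 2 * n_terms)]
  ord <- order(tau); C <- C[ord]; tau <- tau[ord]
  data_resid <- F_obs - model_force(best$par)
  structure(list(C0 = C0, C = C, tau = tau, E_inst = C0 + sum(C),
                 residual_rms = sqrt(mean(data_resid^2)),
                 n_terms = n_terms, n_starts_converged = n_ok,
                 curve = curve, fitted_time = t,
                 fitted = model_force(log(c(C0, C, tau)))),
            class = "prony_fit")
}

#' @export
print.prony_fit <- function(x, ...) {
  cat("Prony-series fit to unconfined force relaxation\n")
  cat(sprintf("  C0 = %.4g kPa, E_inst = %.4g kPa\n", x$C0, x$E_inst))
  print(data.frame(C_kPa = x$C, tau_s = x$tau), row.names = FALSE)
  cat(sprintf("  residual RMS = %.4g mN over %d hold-phase samples\n",
              x$residual_rms, length(x$fitted_time)))
  invisible(x)
}

#' @export
summary.prony_fit <- function(object, ...) {
  g <- prony_to_dimensionless(object)
  out <- list(fit = object, prony = g,
              rel_residual = object$residual_rms / max(object$curve$value))
  class(out) <- "summary.prony_fit"
  out
}

#' @export
print.summary.prony_fit <- function(x, ...) {
  print(x$fit)
  cat("Dimensionless spectrum (g_i = C_i / E_inst):\n")
  print(data.frame(g = x$prony$g, tau_s = x$prony$tau), row.names = FALSE)
  cat(sprintf("relative residual (RMS / peak force) = %.3g\n", x$rel_residual))
  invisible(x)
}

#' @export
coef.prony_fit <- function(object, ...) {
  c(C0 = object$C0,
    stats::setNames(object$C, paste0("C", seq_along(object$C))),
    stats::setNames(object$tau, paste0("tau", seq_along(object$tau))))
}

#' @export
predict.prony_fit <- function(object, t = NULL, ...) {
  if (is.null(t)) t <- object$fitted_time
  unconfined_force_relaxation(object$C0, object$C, object$tau,
                              object$curve$geom, object$curve$loading, t)
}

#' @export
residuals.prony_fit <- function(object, ...) {
  object$curve$value[object$curve$time >= object$curve$loading$t_ramp] - object$fitted
}

#' @export
plot.prony_fit <- function(x, ...) {
  graphics::plot(x$curve$time, x$curve$value, pch = 20, cex = 0.5,
                 xlab = "time (s)", ylab = "force (mN)",
                 main = "Unconfined force relaxation", ...)
  graphics::lines(x$fitted_time, x$fitted, col = 2, lwd = 2)
  graphics::legend("topright", c("data", "Prony fit"), pch = c(20, NA),
                   lty = c(NA, 1), col = c(1, 2), bty = "n")
  invisible(x)
}

#' Convert a Prony fit to the dimensionless relaxation spectrum
#'
#' `g_i = C_i / (C0 + sum_j C_j)`; time constants carry over unchanged.
#'
#' @param fit a `prony_fit`.
#' @return A [prony_series()].
#' @export
prony_to_dimensionless <- function(fit) {
  stopifnot(inherits(fit, "prony_fit"))
  prony_series(g = fit$C / fit$E_inst, tau = fit$tau)
}

#' Fit the Terzaghi consolidation solution to a confined settlement curve
#'
#' Fits `settlement(t) = s_inf * U(c (t - t_ramp) / h^2)` over
#' `{c, s_inf}` by least squares on the hold phase, where `U` is
#' [terzaghi_consolidation()].  If `G` and `nu` (from the unconfined stage)
#' are supplied, the hydraulic conductivity implied by the fitted `c` is also
#' returned.
#'
#' @param curve a [relaxation_curve()] with mode `"confined-settlement"`.
#' @param layer_h drainage-path layer thickness, mm (defaults to the sample
#'   height).
#' @param G,nu optional shear modulus (kPa) and drained Poisson's ratio used
#'   to derive `k` from the fitted `c`.
#' @param seed integer seed for start jitter.
#' @param n_starts number of restarts.
#' @return Object of class `terzaghi_fit` with `c` (mm^2/s),
#'   `settlement_inf` (mm), `k_derived` (mm/s or NA), `residual_rms`.
#' @export
fit_confined <- function(curve, layer_h = NULL, G = NULL, nu = NULL,
                         seed = 1L, n_starts = 5L) {
  stopifnot(inherits(curve, "relaxation_curve"))
  if (curve$mode != "confined-settlement")
    stop("fit_confined() needs a confined-settlement curve")
  h <- if (is.null(layer_h)) curve$geom$height_h else layer_h
  t_ramp <- if (!is.null(curve$loading$t_ramp)) curve$loading$t_ramp else 0
  keep <- curve$time >= t_ramp
  t <- curve$time[keep] - t_ramp; s_obs <- curve$value[keep]
  if (length(t) < 10) stop("no usable hold-phase samples")
  # judge monotonicity on a smoothed record so measurement noise alone
  # (even its extreme excursions) does not trip the warning
  noise_est <- stats::mad(diff(s_obs)) / sqrt(2)
  s_smooth <- stats::lowess(t, s_obs, f = 0.3)$y
  drop <- max(cummax(s_smooth) - s_smooth)
  if (drop > max(3 * noise_est, 0.05 * diff(range(s_obs))))
    warning("settlement record is non-monotone beyond noise tolerance")

  model <- function(lp) exp(lp[2]) * terzaghi_consolidation(exp(lp[1]) * t / h^2)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))

  s_inf0 <- max(s_obs)
  # crude c from the observed half-consolidation time, T50 = 0.197
  i50 <- which(s_obs >= 0.5 * s_inf0)[1]
  c0 <- if (!is.na(i50) && t[i50] > 0) 0.197 * h^2 / t[i50] else h^2 / max(t)

  best <- NULL; best_ss <- Inf
  for (s in seq_len(n_starts)) {
    jit <- if (s == 1) c(1, 1) else exp(stats::rnorm(2, 0, 0.6))
    start <- log(c(c0 * jit[1], s_inf0 * jit[2]))
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start, fn = function(lp) s_obs - model(lp),
                         control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ss <- sum(fit$fvec^2)
    if (ss < best_ss) { best_ss <- ss; best <- fit }
  }
  if (is.null(best))
    stop(sprintf("confined Terzaghi fit failed to converge in %d restarts", n_starts))
  c_fit <- exp(best$par[1]); s_inf <- exp(best$par[2])
  if (c_fit <= 0) stop("fitted consolidation coefficient is non-positive")
  k_derived <- if (!is.null(G) && !is.null(nu)) conductivity_from_c(c_fit, G, nu) else NA_real_
  structure(list(c = c_fit, settlement_inf = s_inf, k_derived = k_derived,
                 residual_rms = sqrt(best_ss / length(t)), layer_h = h,
                 curve = curve, fitted_time = t + t_ramp,
                 fitted = model(best$par)),
            class = "terzaghi_fit")
}

#' @export
print.terzaghi_fit <- function(x, ...) {
  cat("Terzaghi consolidation fit to confined settlement\n")
  cat(sprintf("  c = %.4g mm^2/s, settlement_inf = %.4g mm (layer h = %g mm)\n",
              x$c, x$settlement_inf, x$layer_h))
  if (is.finite(x$k_derived))
    cat(sprintf("  implied hydraulic conductivity k = %.4g mm/s\n", x$k_derived))
  cat(sprintf("  residual RMS = %.4g mm\n", x$residual_rms))
  invisible(x)
}

#' @export
coef.terzaghi_fit <- function(object, ...) {
  c(c = object$c, settlement_inf = object$settlement_inf)
}

#' @export
predict.terzaghi_fit <- function(object, t = NULL, ...) {
  if (is.null(t)) t <- object$fitted_time
  t_ramp <- if (!is.null(object$curve$loading$t_ramp)) object$curve$loading$t_ramp else 0
  object$settlement_inf *
    terzaghi_consolidation(object$c * pmax(t - t_ramp, 0) / object$layer_h^2)
}

#' @export
plot.terzaghi_fit <- function(x, ...) {
  graphics::plot(x$curve$time, x$curve$value, pch = 20, cex = 0.5,
                 xlab = "time (s)", ylab = "settlement (mm)",
                 main = "Confined consolidation", ...)
  graphics::lines(x$fitted_time, x$fitted, col = 2, lwd = 2)
  invisible(x)
}

#' Summarise replicate fits into a parameter range table
#'
#' Collects the coefficients of two or more fits (any mix of `prony_fit` and
#' `terzaghi_fit` objects, summarised separately by class is the caller's
#' choice) into a per-parameter min / max / mean table, the form used to
#' drive material-sensitivity sweeps.
#'
#' @param fits list of >= 2 fit objects with a `coef` method and identical
#'   parameter names.
#' @return data.frame with columns `parameter`, `min`, `max`, `mean`.
#' @export
summarize_replicates <- function(fits) {
  if (!length(fits)) stop("empty fit list")
  if (length(fits) < 2) stop("need at least 2 replicate fits")
  mat <- t(vapply(fits, function(f) stats::coef(f), stats::coef(fits[[1]])))
  data.frame(parameter = colnames(mat),
             min = apply(mat, 2, min),
             max = apply(mat, 2, max),
             mean = colMeans(mat),
             row.names = NULL)
}
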