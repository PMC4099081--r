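# Orchestration: load normalisation, parametric sweeps over the craniectomy
# opening and fillet radius, visco/poro phase decomposition, and
# curve-to-curve comparison metrics.

#' Normalise a load history by its peak
#'
#' `F_n(t) = F(t) / max_t F(t)`; the normalised series attains 1 at the peak,
#' isolating the shape of the relaxation from the magnitude of the elastic
#' response.
#'
#' @param load numeric vector (or a `dc_history`, from which the platen load
#'   is taken).
#' @return Numeric vector with maximum 1.
#' @export
normalize_load <- function(load) {
  if (inherits(load, "dc_history")) load <- load$platen_load
  pk <- max(load)
  if (!is.finite(pk) || pk <= 0) stop("non-positive peak load: cannot normalise")
  load / pk
}

#' Peak shear strain under the craniectomy edge
#'
#' Maximum `|e_rz|` sampled on a horizontal line just under the top surface,
#' at the time of peak load.
#'
#' @param history a `dc_history`.
#' @param depth depth below the top surface of the sampling line, mm.
#' @return List with `value`, `r` (location) and the sampled profile.
#' @keywords internal
peak_edge_shear <- function(history, depth = NULL) {
  geo <- history$config$geometry
  if (is.null(depth)) depth <- 0.75 * history$config$mesh_refinement$fine
  z <- geo$cyl_height - depth
  it <- which.max(history$platen_load)
  prof <- sample_strain(history, list(from = c(0, z), to = c(geo$cyl_radius, z)),
                        time = history$times[it], n = 200)
  i <- which.max(abs(prof$e_rz))
  list(value = abs(prof$e_rz[i]), r = prof$r[i], profile = prof)
}

#' Time to half relaxation of a load history
#'
#' First time at which the load falls below the midpoint between its peak
#' and its final value.
#'
#' @param history a `dc_history`.
#' @return Time, s (NA if the load never crosses the midpoint).
#' @keywords internal
half_relaxation_time <- function(history) {
  f <- history$platen_load; t <- history$times
  ip <- which.max(f)
  target <- (f[ip] + f[length(f)]) / 2
  after <- seq(ip, length(f))
  j <- after[which(f[after] <= target)[1]]
  if (is.na(j)) return(NA_real_)
  if (j == ip) return(t[ip])
  stats::approx(f[c(j - 1, j)], t[c(j - 1, j)], xout = target)$y
}

#' Parametric sweep over craniectomy opening and fillet radius
#'
#' Runs [run_dc_simulation()] for every combination of `a_c` and `R_f`,
#' extracting the peak platen load, the peak shear strain under the
#' craniectomy edge, and the half-relaxation time.  Individual failures are
#' recorded per row and the sweep continues.
#'
#' @param base_config a [dc_config()]; its geometry supplies `cyl_radius`,
#'   `cyl_height`.
#' @param a_c_values,R_f_values vectors of opening and fillet radii, mm.
#' @return Object of class `dc_sweep`: `table` (one row per combination:
#'   `a_c`, `R_f`, `peak_load_mN`, `peak_shear`, `t_half_s`, `error`) and
#'   `histories` (list of `dc_history` or NULL).
#' @export
sweep_craniectomy <- function(base_config, a_c_values, R_f_values) {
  stopifnot(inherits(base_config, "dc_config"))
  grid <- expand.grid(a_c = a_c_values, R_f = R_f_values)
  rows <- vector("list", nrow(grid)); hist <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    res <- tryCatch({
      geo <- craniectomy_geometry(base_config$geometry$cyl_radius,
                                  base_config$geometry$cyl_height,
                                  grid$a_c[i], grid$R_f[i])
      cfg <- base_config; cfg$geometry <- geo
      h <- run_dc_simulation(cfg)
      list(h = h,
           row = data.frame(a_c = grid$a_c[i], R_f = grid$R_f[i],
                            peak_load_mN = max(h$platen_load),
                            peak_shear = peak_edge_shear(h)$value,
                            t_half_s = half_relaxation_time(h),
                            error = NA_character_))
    }, error = function(e)
      list(h = NULL,
           row = data.frame(a_c = grid$a_c[i], R_f = grid$R_f[i],
                            peak_load_mN = NA, peak_shear = NA, t_half_s = NA,
                            error = conditionMessage(e))))
    rows[[i]] <- res$row; hist[[i]] <- res$h
  }
  structure(list(table = do.call(rbind, rows), histories = hist),
            class = "dc_sweep")
}

#' @export
print.dc_sweep <- function(x, ...) {
  cat("Craniectomy parametric sweep\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Compare a candidate load curve against a reference with spread
#'
#' The candidate is linearly resampled onto the reference time grid; returns
#' RMSE, maximum absolute deviation, the fraction of samples inside the
#' `reference +/- spread` band, and the divergence time: the first time the
#' peak-normalised curves differ by more than `tol`.
#'
#' @param ref_time,ref_value reference time series.
#' @param cand_time,cand_value candidate time series (overlapping support).
#' @param spread half-width of the reference band, same units as the values
#'   (scalar or vector on the reference grid); 0 disables the band fraction.
#' @param tol divergence tolerance on the normalised curves (default 0.02).
#' @return List with `rmse`, `max_abs`, `inside_fraction`, `divergence_time`.
#' @export
compare_curves <- function(ref_time, ref_value, cand_time, cand_value,
                           spread = 0, tol = 0.02) {
  if (max(cand_time) < min(ref_time) || min(cand_time) > max(ref_time))
    stop("disjoint time ranges: nothing to compare")
  keep <- ref_time >= min(cand_time) & ref_time <= max(cand_time)
  tt <- ref_time[keep]; rv <- ref_value[keep]
  cv <- stats::approx(cand_time, cand_value, xout = tt)$y
  sp <- if (length(spread) == 1) rep(spread, length(tt)) else spread[keep]
  rmse <- sqrt(mean((cv - rv)^2))
  max_abs <- max(abs(cv - rv))
  inside <- if (all(sp == 0)) NA_real_ else mean(abs(cv - rv) <= sp + 1e-12)
  rn <- rv / max(rv); cn <- cv / max(cv)
  idiv <- which(abs(cn - rn) > tol)[1]
  list(rmse = rmse, max_abs = max_abs, inside_fraction = inside,
       divergence_time = if (is.na(idiv)) NA_real_ else tt[idiv])
}

#' Visco-elastic / poro-elastic phase decomposition
#'
#' Runs the craniectomy model three times with identical geometry and
#' loading: visco-elastic only (hydraulic conductivity scaled up so pore
#' pressures vanish), poro-elastic only (empty Prony spectrum), and the full
#' PVE material.  The normalised load histories expose the two relaxation
#' phases: the early response superposes on the visco-elastic curve, the
#' late response on the poro-elastic one.
#'
#' @param config a [dc_config()].
#' @param k_scale factor by which `k` is multiplied for the visco-only run.
#' @return Object of class `dc_phases` with `times` and normalised loads
#'   `pve`, `visco`, `poro`, plus the three raw histories.
#' @export
phase_decomposition <- function(config, k_scale = 1e6) {
  stopifnot(inherits(config, "dc_config"))
  cfg_v <- config
  cfg_v$material <- poroelastic_params(config$material$E, config$material$nu,
                                       config$material$k * k_scale,
                                       config$material$nu_u)
  cfg_p <- config; cfg_p$prony <- prony_series()
  h_pve <- run_dc_simulation(config)
  h_v <- run_dc_simulation(cfg_v)
  h_p <- run_dc_simulation(cfg_p)
  structure(list(times = h_pve$times,
                 pve = normalize_load(h_pve), visco = normalize_load(h_v),
                 poro = normalize_load(h_p),
                 history_pve = h_pve, history_visco = h_v, history_poro = h_p),
            class = "dc_phases")
}

#' @export
print.dc_phases <- function(x, ...) {
  cat("Phase decomposition (normalised loads at final time):\n")
  n <- length(x$times)
  cat(sprintf("  PVE %.3f | visco-only %.3f | poro-only %.3f\n",
              x$pve[n], x$visco[n], x$poro[n]))
  invisible(x)
}

#' @export
plot.dc_phases <- function(x, ...) {
  graphics::matplot(x$times, cbind(x$pve, x$visco, x$poro), type = "l",
                    lty = c(1, 2, 3), col = c(1, 2, 4), lwd = 2,
                    xlab = "time (s)", ylab = "normalised load", ...)
  graphics::legend("topright", c("PVE", "visco-elastic", "poro-elastic"),
                   lty = c(1, 2, 3), col = c(1, 2, 4), bty = "n")
  invisible(x)
}

#' Demonstration gelatin-like material (synthetic values)
#'
#' Synthetic demonstration parameters for a soft hydrogel: these are not
#' measured values for any particular gel, merely a physically plausible
#' point in the range typical of weak gelatin (tens of kPa stiffness,
#' conductivity giving consolidation over minutes at centimetre scale).
#'
#' @return List with `material` (a [poroelastic_params()]) and `prony`
#'   (a [prony_series()]).
#' @export
dc_demo_material <- function() {
  list(material = poroelastic_params(E = 20, nu = 0.35, k = 2e-5),
       prony = prony_series(g = c(0.3, 0.15), tau = c(1, 10)))
}

#' Demonstration craniectomy configuration (synthetic values)
#'
#' Desk-scale demonstration geometry and loading: a 75 mm radius, 50 mm tall
#' gel cylinder, a craniectomy-like opening of 25 mm radius with a 3 mm edge
#' fillet, and 5 mm of platen displacement at 1 mm/s followed by a 600 s
#' hold (long enough for substantial consolidation at the opening scale,
#' `a_c^2 / c` being a few hundred seconds).  These are plausible bench-rig
#' values, not measurements.
#'
#' @param a_c,R_f opening and fillet radii, mm.
#' @param mesh_fine,mesh_far mesh refinement, mm.
#' @param pore_bc `"permeable"` or `"impermeable"`.
#' @return A [dc_config()].
#' @export
dc_demo_config <- function(a_c = 25, R_f = 3, mesh_fine = 1.5, mesh_far = 7,
                           pore_bc = "permeable") {
  dm <- dc_demo_material()
  dc_config(craniectomy_geometry(75, 50, a_c, R_f),
            dm$material, dm$prony,
            ramp_hold_loading(u_max = 5, t_ramp = 5, t_hold = 600),
            pore_bc = pore_bc,
            mesh_refinement = list(fine = mesh_fine, far = mesh_far))
}

#' Write a simulation configuration to YAML
#'
#' @param config a [dc_config()].
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_dc_config <- function(config, path) {
  stopifnot(inherits(config, "dc_config"))
  yaml::write_yaml(list(
    geometry = unclass(config$geometry),
    material = unclass(config$material)[c("E", "nu", "k", "nu_u")],
    prony = list(g = config$prony$g, tau = config$prony$tau),
    loading = unclass(config$loading),
    pore_bc = config$pore_bc,
    mesh_refinement = config$mesh_refinement), path)
  invisible(path)
}

#' Read a simulation configuration from YAML
#'
#' @param path YAML file written by [write_dc_config()].
#' @return A [dc_config()].
#' @export
read_dc_config <- function(path) {
  y <- yaml::read_yaml(path)
  dc_config(craniectomy_geometry(y$geometry$cyl_radius, y$geometry$cyl_height,
                                 y$geometry$a_c, y$geometry$R_f),
            poroelastic_params(y$material$E, y$material$nu, y$material$k,
                               if (is.null(y$material$nu_u)) 0.5 else y$material$nu_u),
            if (length(y$prony$g)) prony_series(y$prony$g, y$prony$tau)
            else prony_series(),
            ramp_hold_loading(y$loading$u_max, y$loading$t_ramp, y$loading$t_hold),
            pore_bc = y$pore_bc,
            mesh_refinement = y$mesh_refinement)
}
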