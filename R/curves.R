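# Relaxation-curve container and CSV I/O.

#' Sampled relaxation curve
#'
#' Container for a force- or settlement-relaxation record together with the
#' loading metadata needed to fit it.
#'
#' @param time sampling times, s, strictly increasing, `time[1] >= 0`.
#' @param value measured force (mN, unconfined mode) or settlement (mm,
#'   confined mode); no NAs.
#' @param mode `"unconfined-force"` or `"confined-settlement"`.
#' @param geom a [sample_geometry()].
#' @param loading a [ramp_hold_loading()] (unconfined) or a list with at least
#'   `peak_load_N`, `t_ramp` (confined, load-controlled).
#' @return Object of class `relaxation_curve`.
#' @export
relaxation_curve <- function(time, value, mode = c("unconfined-force", "confined-settlement"),
                             geom, loading) {
  mode <- match.arg(mode)
  time <- as.numeric(time); value <- as.numeric(value)
  if (length(time) < 20) stop("a relaxation curve needs at least 20 samples")
  if (length(time) != length(value)) stop("'time' and 'value' lengths differ")
  if (anyNA(time) || anyNA(value)) stop("NAs not allowed in a relaxation curve")
  if (time[1] < 0 || any(diff(time) <= 0)) stop("'time' must be strictly increasing from >= 0")
  stopifnot(inherits(geom, "sample_geometry"))
  structure(list(time = time, value = value, mode = mode,
                 geom = geom, loading = loading),
            class = "relaxation_curve")
}

#' @export
print.relaxation_curve <- function(x, ...) {
  cat(sprintf("Relaxation curve [%s]: %d samples, t in [%g, %g] s\n",
              x$mode, length(x$time), min(x$time), max(x$time)))
  cat(sprintf("  sample: h = %g mm, d = %g mm\n",
              x$geom$height_h, x$geom$diameter_d))
  invisible(x)
}

#' Write a relaxation curve to CSV with a YAML metadata sidecar
#'
#' The CSV has columns `time_s`, `value`; the sidecar `<path>.meta.yaml`
#' records mode, geometry and loading so the curve can be re-read.
#'
#' @param curve a [relaxation_curve()].
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_relaxation_csv <- function(curve, path) {
  stopifnot(inherits(curve, "relaxation_curve"))
  utils::write.csv(data.frame(time_s = curve$time, value = curve$value),
                   path, row.names = FALSE)
  meta <- list(mode = curve$mode,
               geometry = list(height_h = curve$geom$height_h,
                               diameter_d = curve$geom$diameter_d),
               loading = unclass(curve$loading))
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  invisible(path)
}

#' Read a relaxation curve written by [write_relaxation_csv()]
#'
#' @param path CSV file path; the sidecar `<path>.meta.yaml` must exist.
#' @return A [relaxation_curve()].
#' @export
read_relaxation_csv <- function(path) {
  dat <- utils::read.csv(path)
  meta <- yaml::read_yaml(paste0(path, ".meta.yaml"))
  loading <- meta$loading
  if (identical(meta$mode, "unconfined-force"))
    loading <- ramp_hold_loading(loading$u_max, loading$t_ramp, loading$t_hold)
  relaxation_curve(dat$time_s, dat$value, meta$mode,
                   sample_geometry(meta$geometry$height_h, meta$geometry$diameter_d),
                   loading)
}
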