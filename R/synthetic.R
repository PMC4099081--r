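# Seeded generators for every input the pipeline consumes: PVE relaxation
# curves, consolidation settlement curves, and marker image stacks deformed by
# a known displacement field.  Each generator is a pure function of its
# arguments and the seed, and returns the emitted data together with the
# generating ground truth.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  force(expr)
}

#' Generate a synthetic unconfined force-relaxation curve
#'
#' Samples [unconfined_force_relaxation()] over the hold phase and adds
#' i.i.d. Gaussian measurement noise.
#'
#' @param C0,C,tau generating Prony parameters (kPa, kPa, s).
#' @param geom a [sample_geometry()].
#' @param loading a [ramp_hold_loading()].
#' @param noise_sd Gaussian noise standard deviation, mN (>= 0).
#' @param seed integer seed.
#' @param sampling_dt sampling interval, s.
#' @return List with `curve` (a [relaxation_curve()]) and `truth`
#'   (generating parameters and the clean force values).
#' @export
gen_unconfined_curve <- function(C0, C, tau, geom, loading, noise_sd = 0,
                                 seed = 1L, sampling_dt = 0.5) {
  stopifnot(noise_sd >= 0, sampling_dt > 0)
  t <- seq(loading$t_ramp, loading$t_ramp + loading$t_hold, by = sampling_dt)
  clean <- unconfined_force_relaxation(C0, C, tau, geom, loading, t)
  noisy <- with_seed(seed, clean + stats::rnorm(length(t), 0, noise_sd))
  curve <- relaxation_curve(t, noisy, "unconfined-force", geom, loading)
  list(curve = curve,
       truth = list(C0 = C0, C = C, tau = tau, clean = clean,
                    noise_sd = noise_sd, seed = seed))
}

#' Generate a synthetic confined consolidation settlement curve
#'
#' Samples `settlement_inf * U(c t / h^2)` on the hold phase (Terzaghi degree
#' of consolidation `U`) plus Gaussian noise.
#'
#' @param c consolidation coefficient, mm^2/s.
#' @param settlement_inf final settlement, mm.
#' @param h layer thickness / drainage path, mm.
#' @param t_ramp,t_hold load ramp and hold durations, s.
#' @param peak_load_N nominal peak load, N (metadata only).
#' @param noise_sd Gaussian noise sd, mm.
#' @param seed integer seed.
#' @param sampling_dt sampling interval, s.
#' @return List with `curve` and `truth`.
#' @export
gen_confined_curve <- function(c, settlement_inf, h, t_ramp = 1, t_hold = 600,
                               peak_load_N = 1, noise_sd = 0, seed = 1L,
                               sampling_dt = 1) {
  stopifnot(c > 0, settlement_inf > 0, h > 0, noise_sd >= 0)
  t <- seq(t_ramp, t_ramp + t_hold, by = sampling_dt)
  clean <- settlement_inf * terzaghi_consolidation(c * (t - t_ramp) / h^2)
  noisy <- with_seed(seed, clean + stats::rnorm(length(t), 0, noise_sd))
  geom <- sample_geometry(height_h = h, diameter_d = 2 * h)
  curve <- relaxation_curve(t, noisy, "confined-settlement", geom,
                            loading = list(peak_load_N = peak_load_N, t_ramp = t_ramp,
                                           t_hold = t_hold))
  list(curve = curve,
       truth = list(c = c, settlement_inf = settlement_inf, h = h,
                    clean = clean, noise_sd = noise_sd, seed = seed))
}

#' Construct a planar displacement-field evaluator
#'
#' Returns a deterministic function `(x, y, frame)` -> displacement
#' `(dx, dy)` in pixels, ramped linearly from zero at `frame = 1` to the full
#' field at `frame = n_frames` (mimicking a constant platen speed).
#'
#' Kinds:
#' * `"affine"`: `d = A %*% (x, y)` with 2x2 matrix `params$A`.
#' * `"simple-shear"`: `dx = gamma * y`, `dy = 0` with `params$gamma`.
#' * `"bulge"`: Gaussian vertical bulge
#'   `dy = -amp * exp(-((x - x0)^2) / (2 sigma^2))` (upward for positive
#'   `amp` in image coordinates), `dx = 0`; `params$amp`, `params$x0`,
#'   `params$sigma`.
#'
#' @param kind field kind.
#' @param params parameter list for the kind.
#' @param n_frames number of frames over which the ramp completes.
#' @return Function `(x, y, frame)` returning a 2-column matrix `(dx, dy)`.
#' @export
gen_displacement_field <- function(kind = c("affine", "simple-shear", "bulge"),
                                   params = list(), n_frames = 10) {
  kind <- match.arg(kind)
  ramp <- function(frame) if (n_frames <= 1) 1 else (frame - 1) / (n_frames - 1)
  switch(kind,
    "affine" = {
      A <- params$A
      if (is.null(A) || !all(dim(A) == c(2, 2))) stop("affine field needs a 2x2 matrix 'A'")
      function(x, y, frame) ramp(frame) * cbind(A[1, 1] * x + A[1, 2] * y,
                                                A[2, 1] * x + A[2, 2] * y)
    },
    "simple-shear" = {
      gamma <- params$gamma
      if (is.null(gamma)) stop("simple-shear field needs 'gamma'")
      function(x, y, frame) cbind(ramp(frame) * gamma * y, 0 * y)
    },
    "bulge" = {
      amp <- params$amp; x0 <- params$x0; sigma <- params$sigma
      if (is.null(amp) || is.null(x0) || is.null(sigma))
        stop("bulge field needs 'amp', 'x0', 'sigma'")
      function(x, y, frame)
        cbind(0 * x, -ramp(frame) * amp * exp(-(x - x0)^2 / (2 * sigma^2)))
    })
}

# Render one frame: anti-aliased dark disks on a bright background.
render_marker_frame <- function(centres, nx, ny, dot_radius, bg = 0.9, fg = 0.1) {
  img <- matrix(bg, nrow = ny, ncol = nx)  # row = y, col = x
  for (i in seq_len(nrow(centres))) {
    cx <- centres[i, 1]; cy <- centres[i, 2]
    x0 <- max(1L, floor(cx - dot_radius - 1)); x1 <- min(nx, ceiling(cx + dot_radius + 1))
    y0 <- max(1L, floor(cy - dot_radius - 1)); y1 <- min(ny, ceiling(cy + dot_radius + 1))
    xs <- x0:x1; ys <- y0:y1
    d <- sqrt(outer((ys - cy)^2, (xs - cx)^2, "+"))
    cov <- pmin(pmax(dot_radius + 0.5 - d, 0), 1)  # linear edge anti-aliasing
    img[ys, xs] <- img[ys, xs] * (1 - cov) + fg * cov
  }
  img
}

#' Generate a synthetic marker image stack deformed by a known field
#'
#' Renders anti-aliased dark disks (ink markers) at lattice positions
#' displaced by a [gen_displacement_field()] evaluator for each frame, on a
#' bright background, with additive Gaussian noise.  Pixel coordinates:
#' origin top-left, x rightward (columns), y downward (rows).
#'
#' @param rows,cols marker lattice dimensions.
#' @param spacing lattice spacing, px.
#' @param origin lattice origin `(x, y)`, px.
#' @param field displacement evaluator `(x, y, frame) -> cbind(dx, dy)`.
#' @param n_frames number of frames.
#' @param nx,ny image size in pixels (columns, rows).
#' @param dot_radius marker disk radius, px.
#' @param noise_sd additive Gaussian noise sd on the unit-scale image.
#' @param seed integer seed.
#' @return List with `stack` (list of `ny x nx` matrices in `[0,1]`) and
#'   `truth` (array `n_markers x 2 x n_frames` of exact centre trajectories,
#'   plus the lattice reference positions).
#' @export
gen_marker_images <- function(rows = 6, cols = 6, spacing = 24, origin = c(30, 30),
                              field = gen_displacement_field("affine",
                                        list(A = matrix(0, 2, 2))),
                              n_frames = 10, nx = 220, ny = 220,
                              dot_radius = 3, noise_sd = 0, seed = 1L) {
  stopifnot(rows >= 1, cols >= 1, noise_sd >= 0)
  gx <- origin[1] + spacing * (seq_len(cols) - 1)
  gy <- origin[2] + spacing * (seq_len(rows) - 1)
  ref <- as.matrix(expand.grid(x = gx, y = gy))
  n <- nrow(ref)
  truth <- array(NA_real_, dim = c(n, 2, n_frames))
  stack <- vector("list", n_frames)
  with_seed(seed, {
    for (f in seq_len(n_frames)) {
      d <- field(ref[, 1], ref[, 2], f)
      pos <- ref + d
      margin <- dot_radius + 1
      bad <- pos[, 1] < margin | pos[, 1] > nx - margin |
             pos[, 2] < margin | pos[, 2] > ny - margin
      if (any(bad))
        stop(sprintf("marker leaves the frame at frame %d", f))
      truth[, , f] <- pos
      img <- render_marker_frame(pos, nx, ny, dot_radius)
      if (noise_sd > 0)
        img <- pmin(pmax(img + matrix(stats::rnorm(nx * ny, 0, noise_sd), ny, nx), 0), 1)
      stack[[f]] <- img
    }
  })
  list(stack = stack,
       truth = list(reference = ref, trajectories = truth, field = field,
                    seed = seed, dot_radius = dot_radius))
}

#' Write an image stack as numbered PNG files or a multi-page TIFF
#'
#' @param stack list of matrices in `[0, 1]`.
#' @param dir output directory (created if needed) for PNG mode.
#' @param format `"png"` (numbered frames) or `"tiff"` (single multi-page
#'   file at `file.path(dir, "stack.tif")`).
#' @return Character vector of written paths.
#' @export
write_image_stack <- function(stack, dir, format = c("png", "tiff")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (format == "png") {
    if (!requireNamespace("png", quietly = TRUE)) stop("package 'png' not available")
    paths <- file.path(dir, sprintf("frame_%04d.png", seq_along(stack)))
    for (i in seq_along(stack)) png::writePNG(stack[[i]], paths[i])
    paths
  } else {
    if (!requireNamespace("tiff", quietly = TRUE)) stop("package 'tiff' not available")
    path <- file.path(dir, "stack.tif")
    tiff::writeTIFF(stack, path)
    path
  }
}

#' Read an image stack written by [write_image_stack()]
#'
#' @param path directory of numbered PNGs, or a `.tif`/`.tiff` file.
#' @return List of grayscale matrices in `[0, 1]` (multi-channel images are
#'   averaged to grayscale).
#' @export
read_image_stack <- function(path) {
  to_gray <- function(a) if (length(dim(a)) == 3) apply(a[, , 1:min(3, dim(a)[3]), drop = FALSE],
                                                        c(1, 2), mean) else a
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    if (!length(files)) stop("no PNG frames found in ", path)
    lapply(files, function(f) to_gray(png::readPNG(f)))
  } else if (grepl("\\.tiff?$", path)) {
    frames <- tiff::readTIFF(path, all = TRUE)
    lapply(frames, to_gray)
  } else stop("unrecognised image stack path: ", path)
}
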