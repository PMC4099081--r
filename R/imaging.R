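# Marker-based planar strain extraction: detect dark ink markers, link them
# into trajectories across frames, filter and polynomial-smooth the tracks,
# triangulate the reference configuration, and compute a per-triangle strain
# field from the marker displacements (constant-strain triangles).
#
# Image convention: matrices are row = y (downward), col = x (rightward),
# origin at the top-left pixel centre (1, 1); intensities in [0, 1].

#' Detect dark circular markers in a grayscale image
#'
#' Thresholds dark regions, labels connected components (EBImage), filters
#' them by area, and returns darkness-weighted centroids.
#'
#' @param image numeric matrix in `[0, 1]`, row = y, col = x.
#' @param threshold intensity below which a pixel belongs to a marker.
#' @param min_area,max_area component area bounds in pixels.
#' @return Object of class `marker_frame`: data.frame `centroids` with
#'   columns `x`, `y`, `area`, `darkness`.
#' @export
detect_markers <- function(image, threshold = 0.5, min_area = 4, max_area = 500) {
  stopifnot(is.matrix(image))
  mask <- image < threshold
  if (!any(mask)) {
    warning("no markers detected")
    return(structure(list(centroids = data.frame(x = numeric(), y = numeric(),
                                                 area = numeric(), darkness = numeric())),
                     class = "marker_frame"))
  }
  # EBImage images are x-by-y; transpose our row=y matrix
  lab <- EBImage::bwlabel(EBImage::Image(t(mask)))
  labm <- t(EBImage::imageData(lab))              # back to row = y
  ids <- seq_len(max(labm))
  area <- tabulate(labm[labm > 0], nbins = length(ids))
  keep <- which(area >= min_area & area <= max_area)
  if (!length(keep)) {
    warning("no markers within the area bounds")
    return(structure(list(centroids = data.frame(x = numeric(), y = numeric(),
                                                 area = numeric(), darkness = numeric())),
                     class = "marker_frame"))
  }
  # darkness-weighted centroid over the component's bounding box dilated by
  # 2 px, weighting against the background level: thresholding alone clips
  # partially covered edge pixels asymmetrically and pixel-locks the centroid
  bg <- stats::median(image)
  ny <- nrow(image); nx <- ncol(image)
  cx <- cy <- dk <- numeric(length(keep))
  for (j in seq_along(keep)) {
    i <- keep[j]
    pix <- which(labm == i, arr.ind = TRUE)
    y0 <- max(1L, min(pix[, 1]) - 2L); y1 <- min(ny, max(pix[, 1]) + 2L)
    x0 <- max(1L, min(pix[, 2]) - 2L); x1 <- min(nx, max(pix[, 2]) + 2L)
    sub_lab <- labm[y0:y1, x0:x1]
    w <- pmax(bg - image[y0:y1, x0:x1], 0)
    w[sub_lab != 0 & sub_lab != i] <- 0           # exclude other markers
    ws <- sum(w)
    cx[j] <- sum(w * rep(x0:x1, each = y1 - y0 + 1)) / ws
    cy[j] <- sum(w * rep(y0:y1, times = x1 - x0 + 1)) / ws
    dk[j] <- sum(w[sub_lab == i]) / area[i]
  }
  ord <- order(cy, cx)
  structure(list(centroids = data.frame(x = cx, y = cy, area = area[keep],
                                        darkness = dk)[ord, , drop = FALSE]),
            class = "marker_frame")
}

#' @export
print.marker_frame <- function(x, ...) {
  cat(sprintf("Marker frame: %d detections\n", nrow(x$centroids)))
  invisible(x)
}

#' Link marker detections into trajectories
#'
#' Frame-to-frame assignment by mutual nearest neighbours within `max_disp`
#' pixels, conflicts resolved by smallest distance (ties by marker index).
#' Tracks missing a detection are suspended for up to `memory` frames and can
#' resume (presence gaps); unmatched detections open new tracks.
#'
#' @param frames list of `marker_frame` objects (>= 2).
#' @param max_disp maximum displacement per frame, px.
#' @param memory frames a suspended track survives before being closed.
#' @return Object of class `marker_tracks`: arrays `x`, `y`
#'   (`n_tracks x n_frames`, NA where absent) and a logical `present` mask.
#' @export
link_tracks <- function(frames, max_disp = 10, memory = 2) {
  stopifnot(length(frames) >= 2)
  nf <- length(frames)
  first <- frames[[1]]$centroids
  tr_x <- matrix(NA_real_, nrow(first), nf); tr_y <- tr_x
  tr_x[, 1] <- first$x; tr_y[, 1] <- first$y
  last_seen <- rep(1L, nrow(first))
  for (f in 2:nf) {
    det <- frames[[f]]$centroids
    nd <- nrow(det)
    active <- which(f - last_seen <= memory)
    if (nd && length(active)) {
      lx <- vapply(active, function(i) tr_x[i, last_seen[i]], numeric(1))
      ly <- vapply(active, function(i) tr_y[i, last_seen[i]], numeric(1))
      dmat <- sqrt(outer(lx, det$x, "-")^2 + outer(ly, det$y, "-")^2)
      dmat[dmat > max_disp] <- Inf
      # mutual nearest neighbours, conflicts by distance then index
      cand <- which(is.finite(dmat), arr.ind = TRUE)
      if (nrow(cand)) {
        dd <- dmat[cand]
        ord <- order(dd, cand[, 1], cand[, 2])
        used_t <- logical(length(active)); used_d <- logical(nd)
        for (kk in ord) {
          ti <- cand[kk, 1]; di <- cand[kk, 2]
          if (used_t[ti] || used_d[di]) next
          # mutual-NN among unused candidates
          if (dmat[ti, di] <= min(dmat[ti, !used_d], Inf) + 1e-12 &&
              dmat[ti, di] <= min(dmat[!used_t, di], Inf) + 1e-12) {
            row <- active[ti]
            tr_x[row, f] <- det$x[di]; tr_y[row, f] <- det$y[di]
            last_seen[row] <- f
            used_t[ti] <- TRUE; used_d[di] <- TRUE
          }
        }
        new_d <- which(!used_d)
      } else new_d <- seq_len(nd)
    } else new_d <- seq_len(nd)
    if (length(new_d)) {          # open new tracks
      add_x <- matrix(NA_real_, length(new_d), nf); add_y <- add_x
      add_x[, f] <- det$x[new_d]; add_y[, f] <- det$y[new_d]
      tr_x <- rbind(tr_x, add_x); tr_y <- rbind(tr_y, add_y)
      last_seen <- c(last_seen, rep(f, length(new_d)))
    }
  }
  structure(list(x = tr_x, y = tr_y, present = !is.na(tr_x),
                 n_frames = nf, smoothed = FALSE),
            class = "marker_tracks")
}

#' @export
print.marker_tracks <- function(x, ...) {
  cat(sprintf("Marker tracks: %d tracks over %d frames (%s)\n",
              nrow(x$x), x$n_frames,
              if (isTRUE(x$smoothed)) "smoothed" else "raw"))
  cat(sprintf("  median presence fraction %.2f\n",
              stats::median(rowMeans(x$present))))
  invisible(x)
}

#' Filter short tracks and smooth with time polynomials
#'
#' Tracks present in fewer than `min_fraction` of frames (or with fewer than
#' `poly_order + 1` detections) are discarded; surviving tracks are
#' least-squares fitted with order-`poly_order` polynomials in the frame
#' index for each coordinate, which both smooths the positions and
#' interpolates missing frames.
#'
#' @param tracks a `marker_tracks` object.
#' @param min_fraction minimum presence fraction in (0, 1].
#' @param poly_order polynomial order (default 2).
#' @return A `marker_tracks` object with complete smoothed positions and the
#'   polynomial coefficients in `coef_x`, `coef_y`; the raw positions are
#'   kept in `raw_x`, `raw_y`.
#' @export
filter_and_smooth_tracks <- function(tracks, min_fraction = 0.5, poly_order = 2) {
  stopifnot(inherits(tracks, "marker_tracks"),
            min_fraction > 0, min_fraction <= 1)
  nf <- tracks$n_frames
  frac <- rowMeans(tracks$present)
  npts <- rowSums(tracks$present)
  keep <- frac >= min_fraction & npts >= poly_order + 1
  if (any(frac >= min_fraction & npts < poly_order + 1))
    message(sum(frac >= min_fraction & npts < poly_order + 1),
            " track(s) shorter than poly_order + 1 points removed")
  if (!any(keep)) stop("no tracks survive filtering")
  x <- tracks$x[keep, , drop = FALSE]; y <- tracks$y[keep, , drop = FALSE]
  tt <- seq_len(nf)
  Xd <- stats::poly(tt, degree = poly_order, raw = TRUE)
  sm_x <- matrix(NA_real_, nrow(x), nf); sm_y <- sm_x
  cfx <- matrix(NA_real_, nrow(x), poly_order + 1); cfy <- cfx
  for (i in seq_len(nrow(x))) {
    pres <- tracks$present[which(keep)[i], ]
    fx <- stats::lm.fit(cbind(1, Xd[pres, , drop = FALSE]), x[i, pres])
    fy <- stats::lm.fit(cbind(1, Xd[pres, , drop = FALSE]), y[i, pres])
    cfx[i, ] <- fx$coefficients; cfy[i, ] <- fy$coefficients
    sm_x[i, ] <- cbind(1, Xd) %*% fx$coefficients
    sm_y[i, ] <- cbind(1, Xd) %*% fy$coefficients
  }
  structure(list(x = sm_x, y = sm_y, present = matrix(TRUE, nrow(x), nf),
                 raw_x = x, raw_y = y, raw_present = tracks$present[keep, , drop = FALSE],
                 coef_x = cfx, coef_y = cfy,
                 n_frames = nf, smoothed = TRUE),
            class = "marker_tracks")
}

#' Delaunay triangulation of reference marker positions
#'
#' @param reference_positions 2-column matrix (x, y), >= 3 non-collinear
#'   points.
#' @return Integer matrix `n_triangles x 3` of vertex indices into
#'   `reference_positions`.
#' @export
triangulate <- function(reference_positions) {
  pts <- as.matrix(reference_positions)
  if (nrow(pts) < 3) stop("need at least 3 points to triangulate")
  ex <- diff(range(pts[, 1])); ey <- diff(range(pts[, 2]))
  sv <- svd(scale(pts, scale = FALSE))$d
  if (sv[2] < 1e-9 * max(sv[1], 1))
    stop("points are collinear: no triangulation exists")
  if (nrow(pts) == 3) return(matrix(1:3, nrow = 1))
  dd <- deldir::deldir(pts[, 1], pts[, 2], suppressMsge = TRUE)
  tri <- deldir::triMat(dd)
  colnames(tri) <- NULL
  tri
}

#' Per-triangle strain field from marker displacements
#'
#' For each (constant-strain) triangle the deformation gradient `F` is
#' obtained from the reference and displaced vertex positions; the reported
#' measure is the Green-Lagrange tensor `E = (F'F - I) / 2` (exact under
#' rigid rotations), with the small-strain tensor
#' `eps = (F + F') / 2 - I` as an option.
#'
#' @param triangles index matrix from [triangulate()].
#' @param reference_positions,displaced_positions 2-column matrices; the
#'   displaced matrix may be a 3-D array `n x 2 x n_frames` for a whole
#'   stack.
#' @param measure `"green-lagrange"` (default) or `"small"`.
#' @param min_area triangles with reference area below this (px^2) are
#'   flagged invalid (NA strain).
#' @param min_quality minimum shape quality `4 sqrt(3) area / sum(edge^2)`
#'   (1 for equilateral, 0 for degenerate); slivers formed by nearly
#'   collinear boundary markers amplify centroid noise and are flagged
#'   invalid.
#' @return Object of class `strain_field`: `triangles`, `centroids`
#'   (reference), and `strain`, an array `n_triangles x 3 x n_frames` of
#'   `(E_xx, E_yy, E_xy)`.
#' @export
compute_strain_field <- function(triangles, reference_positions, displaced_positions,
                                 measure = c("green-lagrange", "small"),
                                 min_area = 1e-6, min_quality = 0.05) {
  measure <- match.arg(measure)
  ref <- as.matrix(reference_positions)
  disp <- displaced_positions
  if (length(dim(disp)) == 2) disp <- array(disp, dim = c(dim(disp), 1))
  nfr <- dim(disp)[3]
  ntri <- nrow(triangles)
  if (max(triangles) > nrow(ref) || max(triangles) > dim(disp)[1])
    stop("displaced positions missing for some referenced markers")
  strain <- array(NA_real_, dim = c(ntri, 3, nfr),
                  dimnames = list(NULL, c("E_xx", "E_yy", "E_xy"), NULL))
  cent <- matrix(NA_real_, ntri, 2)
  valid <- logical(ntri)
  for (k in seq_len(ntri)) {
    v <- triangles[k, ]
    X <- ref[v, , drop = FALSE]
    cent[k, ] <- colMeans(X)
    DX <- cbind(X[2, ] - X[1, ], X[3, ] - X[1, ])      # 2 x 2, columns = edges
    area2 <- abs(det(DX))
    edge2 <- sum((X[2, ] - X[1, ])^2) + sum((X[3, ] - X[2, ])^2) +
             sum((X[1, ] - X[3, ])^2)
    quality <- 2 * sqrt(3) * area2 / edge2
    if (area2 < 2 * min_area || quality < min_quality) next   # degenerate/sliver
    valid[k] <- TRUE
    DXinv <- solve(DX)
    for (f in seq_len(nfr)) {
      xk <- disp[v, , f]
      Dx <- cbind(xk[2, ] - xk[1, ], xk[3, ] - xk[1, ])
      Fg <- Dx %*% DXinv
      Em <- if (measure == "green-lagrange") (crossprod(Fg) - diag(2)) / 2
            else (Fg + t(Fg)) / 2 - diag(2)
      strain[k, , f] <- c(Em[1, 1], Em[2, 2], Em[1, 2])
    }
  }
  if (any(!valid))
    message(sum(!valid), " degenerate triangle(s) flagged invalid")
  structure(list(triangles = triangles, centroids = cent, strain = strain,
                 valid = valid, measure = measure),
            class = "strain_field")
}

#' @export
print.strain_field <- function(x, ...) {
  cat(sprintf("Strain field: %d triangles, %d frame(s), measure = %s\n",
              nrow(x$triangles), dim(x$strain)[3], x$measure))
  fin <- x$strain[x$valid, , dim(x$strain)[3]]
  if (length(fin))
    cat(sprintf("  final-frame ranges: E_xx [%.4g, %.4g], E_yy [%.4g, %.4g], E_xy [%.4g, %.4g]\n",
                min(fin[, 1]), max(fin[, 1]), min(fin[, 2]), max(fin[, 2]),
                min(fin[, 3]), max(fin[, 3])))
  invisible(x)
}

#' Sample a strain component along a line through the marker field
#'
#' Selects triangles whose (reference) centroids lie within
#' `band_halfwidth` of the line and orders them by position along it.
#'
#' @param field a `strain_field`.
#' @param line list with `from = c(x, y)`, `to = c(x, y)` (px, reference
#'   coordinates).
#' @param band_halfwidth half-width of the selection band, px.
#' @param component `"E_xx"`, `"E_yy"` or `"E_xy"`.
#' @param frame frame index (default last).
#' @return data.frame with `s` (position along the line), `x`, `y`, and the
#'   component value, ordered by `s`.
#' @export
sample_strain_along_line <- function(field, line, band_halfwidth,
                                     component = c("E_xy", "E_xx", "E_yy"),
                                     frame = NULL) {
  stopifnot(inherits(field, "strain_field"))
  component <- match.arg(component)
  if (is.null(frame)) frame <- dim(field$strain)[3]
  a <- as.numeric(line$from); b <- as.numeric(line$to)
  dvec <- b - a; len <- sqrt(sum(dvec^2))
  if (len <= 0) stop("degenerate line")
  u <- dvec / len
  rel <- sweep(field$centroids, 2, a)
  s <- rel %*% u
  perp <- abs(rel[, 1] * u[2] - rel[, 2] * u[1])
  sel <- which(perp <= band_halfwidth & s >= -band_halfwidth &
                 s <= len + band_halfwidth & field$valid)
  if (!length(sel))
    stop("no triangle centroids within the band; try a larger band_halfwidth")
  ord <- sel[order(s[sel])]
  data.frame(s = as.numeric(s[ord]),
             x = field$centroids[ord, 1], y = field$centroids[ord, 2],
             value = field$strain[ord, component, frame])
}

#' Run the full imaging pipeline on an image stack
#'
#' Convenience wrapper: detect markers in every frame, link, filter/smooth,
#' triangulate the first smoothed frame, and compute the per-triangle strain
#' field for all frames.
#'
#' @param stack list of grayscale matrices.
#' @param threshold,min_area,max_area see [detect_markers()].
#' @param max_disp,memory see [link_tracks()].
#' @param min_fraction see [filter_and_smooth_tracks()].
#' @param measure see [compute_strain_field()].
#' @return List with `tracks`, `triangles`, `field`.
#' @export
track_strain_pipeline <- function(stack, threshold = 0.5, min_area = 4,
                                  max_area = 500, max_disp = 10, memory = 2,
                                  min_fraction = 0.5,
                                  measure = "green-lagrange") {
  frames <- lapply(stack, detect_markers, threshold = threshold,
                   min_area = min_area, max_area = max_area)
  tracks <- filter_and_smooth_tracks(link_tracks(frames, max_disp, memory),
                                     min_fraction = min_fraction)
  ref <- cbind(tracks$x[, 1], tracks$y[, 1])
  tri <- triangulate(ref)
  disp <- array(c(tracks$x, tracks$y), dim = c(nrow(tracks$x), tracks$n_frames, 2))
  disp <- aperm(disp, c(1, 3, 2))
  field <- compute_strain_field(tri, ref, disp, measure = measure)
  list(tracks = tracks, triangles = tri, field = field)
}
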