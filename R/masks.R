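#' Rasterize one contoured structure onto a grid
#'
#' A voxel is set iff its centre lies inside the polygon(s) of the nearest
#' contour plane, where "nearest" requires `|z_centre - z_plane| <= sz / 2`.
#' Inclusion uses the even-odd rule, so multiple polygons on one plane
#' describe holes/islands; points exactly on a polygon edge count as inside.
#' This voxel-centre convention keeps rasterized volumes consistent with how
#' gamma and DVH metrics are scored (whole voxels, no partial-volume
#' weighting).
#'
#' @param contours a [contour_set()].
#' @param name name of the structure to rasterize.
#' @param header target [grid_header()].
#' @return A [voxel_mask()] on `header`.
#' @export
rasterize_contours <- function(contours, name, header) {
  stopifnot(inherits(contours, "contour_set"), inherits(header, "grid_header"))
  if (!name %in% names(contours$structures))
    stop(sprintf("structure '%s' not present in contour set", name), call. = FALSE)
  polys <- contours$structures[[name]]
  flags <- array(FALSE, dim = header$dims)
  if (length(polys) == 0L) {
    warning(sprintf("structure '%s' has no polygons; returning empty mask", name), call. = FALSE)
    return(voxel_mask(header, as.vector(flags)))
  }
  zc <- axis_coords(header, 3)
  sz <- header$spacing[3]
  xc <- axis_coords(header, 1)
  yc <- axis_coords(header, 2)
  dropped <- 0L
  for (p in polys) {
    # slice(s) whose centre is within half a spacing of the contour plane;
    # the nearest-plane rule means each polygon claims at most one slice
    dz <- abs(zc - p$z)
    iz <- which(dz <= sz / 2 + 1e-9)
    if (length(iz) == 0L) { dropped <- dropped + 1L; next }
    iz <- iz[which.min(dz[iz])]
    inside <- point_in_polygon_grid(xc, yc, p$xy)
    flags[, , iz] <- xor(flags[, , iz], inside)
  }
  if (dropped > 0L)
    warning(sprintf("%d polygon(s) of '%s' lie outside the grid z-extent and were ignored",
                    dropped, name), call. = FALSE)
  voxel_mask(header, as.vector(flags))
}

# Even-odd (crossing-number) test of all grid points (xs x ys) against one
# polygon, vectorized over grid points edge by edge. Points exactly on an
# edge are forced inside.
point_in_polygon_grid <- function(xs, ys, poly_xy) {
  nx <- length(xs); ny <- length(ys)
  px <- rep(xs, times = ny)
  py <- rep(ys, each = nx)
  vx <- poly_xy[, 1]; vy <- poly_xy[, 2]
  n <- length(vx)
  crossings <- integer(nx * ny)
  on_edge <- logical(nx * ny)
  jx <- vx[c(n, seq_len(n - 1L))]
  jy <- vy[c(n, seq_len(n - 1L))]
  for (k in seq_len(n)) {
    x1 <- jx[k]; y1 <- jy[k]; x2 <- vx[k]; y2 <- vy[k]
    # half-open rule on y avoids double counting at shared vertices
    straddles <- (y1 > py) != (y2 > py)
    if (any(straddles)) {
      xin <- x1 + (py[straddles] - y1) / (y2 - y1) * (x2 - x1)
      crossings[straddles] <- crossings[straddles] + (px[straddles] < xin)
      # points exactly on a non-horizontal edge
      hit <- straddles
      hit[straddles] <- abs(px[straddles] - xin) < 1e-9
      on_edge <- on_edge | hit
    }
    # horizontal or generic collinear-on-segment check
    dx <- x2 - x1; dy <- y2 - y1
    seg_len2 <- dx * dx + dy * dy
    if (seg_len2 > 0) {
      t <- ((px - x1) * dx + (py - y1) * dy) / seg_len2
      t <- pmin(pmax(t, 0), 1)
      d2 <- (x1 + t * dx - px)^2 + (y1 + t * dy - py)^2
      on_edge <- on_edge | (d2 < 1e-18)
    }
  }
  (crossings %% 2L == 1L) | on_edge
}

#' Volume of a voxel mask in cc
#'
#' Counts set voxels and multiplies by the voxel volume
#' `sx * sy * sz / 1000` (mm^3 to cc). This voxelized volume is the quantity
#' paired with the gamma passing rate in the cohort regression, so both are
#' measured on exactly the same voxel set.
#'
#' @param mask a [voxel_mask()].
#' @return Volume in cc.
#' @examples
#' h <- grid_header(c(4, 4, 4), spacing = c(2.5, 2.5, 2.5))
#' volume_cc(voxel_mask(h, rep(1, 64)))  # 64 voxels x 0.015625 cc = 1 cc
#' @export
volume_cc <- function(mask) {
  stopifnot(inherits(mask, "voxel_mask"))
  sum(mask$flags) * prod(mask$header$spacing) / 1000
}

#' Combine two voxel masks
#'
#' @param a,b [voxel_mask()] objects on identical grid headers.
#' @param op one of `"union"`, `"intersect"`, `"subtract"` (a minus b).
#' @return A [voxel_mask()].
#' @export
combine_masks <- function(a, b, op = c("union", "intersect", "subtract")) {
  op <- match.arg(op)
  stopifnot(inherits(a, "voxel_mask"), inherits(b, "voxel_mask"))
  stop_if_geometry_differs(a$header, b$header, "masks")
  flags <- switch(op,
                  union = a$flags | b$flags,
                  intersect = a$flags & b$flags,
                  subtract = a$flags & !b$flags)
  voxel_mask(a$header, flags)
}

#' Extract the interface shell of a mask
#'
#' The shell is the set of voxels removed by `k` iterations of 6-connected
#' morphological erosion, with `k = round(thickness_mm / min(spacing))`.
#' Voxels outside the grid count as background, so the mask also erodes at
#' grid boundaries. Used to localize interface dose perturbations (e.g.
#' electronic-disequilibrium underdosage at air/tissue interfaces).
#'
#' @param mask a [voxel_mask()].
#' @param thickness_mm shell thickness in mm (> 0).
#' @return A [voxel_mask()]; a subset of `mask`.
#' @export
interface_shell <- function(mask, thickness_mm) {
  stopifnot(inherits(mask, "voxel_mask"))
  if (!is.numeric(thickness_mm) || thickness_mm <= 0)
    stop("`thickness_mm` must be > 0", call. = FALSE)
  k <- round(thickness_mm / min(mask$header$spacing))
  if (k == 0) {
    warning("shell thickness below half a voxel: returning empty shell", call. = FALSE)
    return(voxel_mask(mask$header, rep(FALSE, n_voxels(mask$header))))
  }
  eroded <- array(mask$flags, dim = mask$header$dims)
  for (i in seq_len(k)) eroded <- erode6(eroded)
  voxel_mask(mask$header, mask$flags & !as.vector(eroded))
}

# one step of 6-connected erosion with background outside the grid
erode6 <- function(m) {
  d <- dim(m)
  shift <- function(arr, axis, by) {
    out <- array(FALSE, dim = d)
    if (axis == 1) {
      if (by == 1) out[2:d[1], , ] <- arr[1:(d[1] - 1), , ]
      else out[1:(d[1] - 1), , ] <- arr[2:d[1], , ]
    } else if (axis == 2) {
      if (by == 1) out[, 2:d[2], ] <- arr[, 1:(d[2] - 1), ]
      else out[, 1:(d[2] - 1), ] <- arr[, 2:d[2], ]
    } else {
      if (by == 1) out[, , 2:d[3]] <- arr[, , 1:(d[3] - 1)]
      else out[, , 1:(d[3] - 1)] <- arr[, , 2:d[3]]
    }
    out
  }
  res <- m
  for (axis in 1:3) {
    if (d[axis] == 1) { res[] <- FALSE; next }
    res <- res & shift(m, axis, 1) & shift(m, axis, -1)
  }
  res
}
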