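#' Grid header: geometry shared by dose grids and masks
#'
#' A `grid_header` describes an axis-aligned, uniformly spaced 3D voxel grid
#' in patient-space millimetres. Voxel centres sit at
#' `origin + index * spacing` with 0-based indices; storage order is
#' x-fastest (x, then y, then z), matching the DICOM RT Dose frame layout.
#'
#' @param dims integer vector of length 3: number of voxels (nx, ny, nz),
#'   each at least 1.
#' @param origin numeric vector of length 3: position (mm) of the centre of
#'   voxel (0, 0, 0).
#' @param spacing numeric vector of length 3: voxel spacing (mm) per axis,
#'   all strictly positive.
#' @return An object of class `grid_header`.
#' @examples
#' grid_header(c(64, 64, 64), c(-78.75, -78.75, -78.75), c(2.5, 2.5, 2.5))
#' @export
grid_header <- function(dims, origin = c(0, 0, 0), spacing = c(2.5, 2.5, 2.5)) {
  dims <- as.integer(dims)
  origin <- as.numeric(origin)
  spacing <- as.numeric(spacing)
  if (length(dims) != 3L || anyNA(dims) || any(dims < 1L))
    stop("`dims` must be 3 integers, all >= 1", call. = FALSE)
  if (length(origin) != 3L || !all(is.finite(origin)))
    stop("`origin` must be 3 finite numbers (mm)", call. = FALSE)
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive numbers (mm)", call. = FALSE)
  structure(list(dims = dims, origin = origin, spacing = spacing),
            class = "grid_header")
}

#' @export
print.grid_header <- function(x, ...) {
  cat(sprintf("<grid_header> %d x %d x %d voxels, spacing (%g, %g, %g) mm, origin (%g, %g, %g) mm\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

n_voxels <- function(header) prod(header$dims)

#' Test two grid headers for exact equality
#'
#' Headers are equal only when dims, origin and spacing match exactly; the
#' package never resamples, so any mismatch is treated as a hard geometry
#' error by downstream operations.
#'
#' @param a,b `grid_header` objects.
#' @return `TRUE` or `FALSE`.
#' @export
same_geometry <- function(a, b) {
  identical(a$dims, b$dims) &&
    identical(as.numeric(a$origin), as.numeric(b$origin)) &&
    identical(as.numeric(a$spacing), as.numeric(b$spacing))
}

stop_if_geometry_differs <- function(a, b, what = "grids") {
  if (!same_geometry(a, b))
    stop(sprintf("geometry error: %s do not share an identical grid header (no implicit resampling)", what),
         call. = FALSE)
  invisible(TRUE)
}

#' Dose grid: 3D absorbed-dose array with geometry
#'
#' @param header a [grid_header()].
#' @param values numeric vector of absorbed dose in Gy, x-fastest order,
#'   length `prod(dims)`; all values must be finite and non-negative.
#' @return An object of class `dose_grid` with fields `header` and `values`.
#' @examples
#' h <- grid_header(c(2, 2, 1))
#' dose_grid(h, c(1, 2, 3, 4))
#' @export
dose_grid <- function(header, values) {
  stopifnot(inherits(header, "grid_header"))
  values <- as.numeric(values)
  if (length(values) != n_voxels(header))
    stop(sprintf("size error: expected %d dose values, got %d",
                 n_voxels(header), length(values)), call. = FALSE)
  if (!all(is.finite(values)))
    stop("domain error: dose values must be finite", call. = FALSE)
  if (any(values < 0))
    stop("domain error: negative dose values are not allowed", call. = FALSE)
  structure(list(header = header, values = values), class = "dose_grid")
}

#' Voxel mask: boolean ROI aligned to a grid
#'
#' @param header a [grid_header()].
#' @param flags logical (or 0/1) vector, x-fastest order, length `prod(dims)`.
#' @return An object of class `voxel_mask` with fields `header` and `flags`.
#' @export
voxel_mask <- function(header, flags) {
  stopifnot(inherits(header, "grid_header"))
  if (is.numeric(flags)) {
    if (!all(flags %in% c(0, 1)))
      stop("domain error: mask values must be 0 or 1", call. = FALSE)
    flags <- flags != 0
  }
  flags <- as.logical(flags)
  if (length(flags) != n_voxels(header))
    stop(sprintf("size error: expected %d mask values, got %d",
                 n_voxels(header), length(flags)), call. = FALSE)
  if (anyNA(flags))
    stop("domain error: mask values must be 0 or 1", call. = FALSE)
  structure(list(header = header, flags = flags), class = "voxel_mask")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose_grid> %d x %d x %d voxels, dose range [%.4g, %.4g] Gy\n",
              x$header$dims[1], x$header$dims[2], x$header$dims[3],
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.voxel_mask <- function(x, ...) {
  cat(sprintf("<voxel_mask> %d x %d x %d voxels, %d set (%.3g cc)\n",
              x$header$dims[1], x$header$dims[2], x$header$dims[3],
              sum(x$flags), volume_cc(x)))
  invisible(x)
}

#' @export
as.array.dose_grid <- function(x, ...) array(x$values, dim = x$header$dims)

#' @export
as.array.voxel_mask <- function(x, ...) array(x$flags, dim = x$header$dims)

# voxel-centre coordinates (mm) along one axis: origin + 0:(n-1) * spacing
axis_coords <- function(header, axis) {
  header$origin[axis] + (seq_len(header$dims[axis]) - 1) * header$spacing[axis]
}

# linear (1-based) index from 0-based (ix, iy, iz); x-fastest
linear_index <- function(header, ix, iy, iz) {
  1L + ix + header$dims[1] * (iy + header$dims[2] * iz)
}
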