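#' Axis-aligned 3D scalar grid
#'
#' A `dose_grid` holds a scalar field (dose in Gy, or any unitless quantity)
#' on an axis-aligned voxel grid in patient coordinates (mm, DICOM LPS:
#' x toward patient left, y toward posterior, z toward superior). Values are
#' stored as an array with dimensions ordered (x, y, z) and are sampled at
#' voxel centers. Only the identity orientation (head-first supine) is
#' supported; oblique grids are rejected.
#'
#' @param values Numeric 3D array, dimensions (nx, ny, nz).
#' @param origin Length-3 numeric, patient-mm coordinates of the center of
#'   voxel (1, 1, 1).
#' @param spacing Length-3 numeric, strictly positive per-axis spacing in mm.
#' @param require_nonneg If `TRUE` (default), reject negative values — dose
#'   cannot be negative.
#' @return An object of class `dose_grid`.
#' @export
dose_grid <- function(values, origin, spacing, require_nonneg = TRUE) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    rlang::abort("`values` must be a 3D array.")
  }
  origin <- as.numeric(origin)
  spacing <- as.numeric(spacing)
  if (length(origin) != 3L || length(spacing) != 3L) {
    rlang::abort("`origin` and `spacing` must have length 3.")
  }
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    rlang::abort("`spacing` must be strictly positive and finite.")
  }
  if (any(!is.finite(values))) {
    rlang::abort("grid values must all be finite.")
  }
  if (require_nonneg && any(values < 0)) {
    rlang::abort("dose values must be non-negative.")
  }
  structure(
    list(values = values, origin = origin, spacing = spacing),
    class = "dose_grid"
  )
}

#' Grid geometry without values
#'
#' Extracts the geometry (origin, spacing, shape) of a grid or mask, for use
#' as a destination geometry in [resample_grid()] or [rasterize()].
#'
#' @param x A `dose_grid` or `binary_mask`.
#' @return A list with elements `origin`, `spacing`, `shape`.
#' @export
grid_geometry <- function(x) {
  if (inherits(x, c("binary_mask", "parotid_labelmap"))) x <- x$grid
  if (inherits(x, "dose_grid")) {
    return(list(origin = x$origin, spacing = x$spacing, shape = dim(x$values)))
  }
  if (is.list(x) && all(c("origin", "spacing", "shape") %in% names(x))) {
    return(list(origin = as.numeric(x$origin), spacing = as.numeric(x$spacing),
                shape = as.integer(x$shape)))
  }
  rlang::abort("cannot extract a grid geometry from `x`.")
}

#' Construct a grid geometry from scratch
#'
#' @param origin,spacing Length-3 numeric (mm).
#' @param shape Length-3 integer voxel counts.
#' @return A geometry list accepted wherever a grid geometry is expected.
#' @export
make_geometry <- function(origin, spacing, shape) {
  list(origin = as.numeric(origin), spacing = as.numeric(spacing),
       shape = as.integer(shape))
}

#' Voxel-center coordinates along each axis
#' @param geom A grid geometry (or grid/mask).
#' @return List of numeric vectors `x`, `y`, `z` (mm).
#' @export
axis_coords <- function(geom) {
  g <- grid_geometry(geom)
  list(
    x = g$origin[1] + (seq_len(g$shape[1]) - 1) * g$spacing[1],
    y = g$origin[2] + (seq_len(g$shape[2]) - 1) * g$spacing[2],
    z = g$origin[3] + (seq_len(g$shape[3]) - 1) * g$spacing[3]
  )
}

#' @export
print.dose_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<dose_grid> %d x %d x %d voxels, spacing (%.3g, %.3g, %.3g) mm\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]
  ))
  cat(sprintf("  origin (%.2f, %.2f, %.2f) mm; range [%.4g, %.4g]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$values), max(x$values)))
  invisible(x)
}

#' Binary voxel mask on a grid geometry
#'
#' @param voxels Logical 3D array.
#' @param geom Grid geometry the mask lives on (same shape as `voxels`).
#' @return An object of class `binary_mask` with elements `voxels` and `grid`.
#' @export
binary_mask <- function(voxels, geom) {
  g <- grid_geometry(geom)
  if (!is.array(voxels) || !is.logical(voxels) ||
      !identical(dim(voxels), as.integer(g$shape))) {
    rlang::abort("`voxels` must be a logical array matching the geometry shape.")
  }
  structure(list(voxels = voxels, grid = g), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d / %d voxels set (%.2f cc)\n",
              sum(x$voxels), length(x$voxels), mask_volume_cc(x)))
  invisible(x)
}

#' Mask volume in cc
#'
#' Voxel count times voxel volume; 1 cc = 1000 mm^3.
#' @param mask A `binary_mask`.
#' @return Volume in cc.
#' @export
mask_volume_cc <- function(mask) {
  sum(mask$voxels) * prod(mask$grid$spacing) / 1000
}

same_geometry <- function(a, b, tol = 1e-6) {
  ga <- grid_geometry(a); gb <- grid_geometry(b)
  identical(as.integer(ga$shape), as.integer(gb$shape)) &&
    max(abs(ga$origin - gb$origin)) < tol &&
    max(abs(ga$spacing - gb$spacing)) < tol
}

#' Resample a grid onto a new geometry by trilinear interpolation
#'
#' Values inside the source support are trilinearly interpolated; destination
#' voxels outside the source bounding box get 0. On an identical geometry the
#' result is bitwise equal to the source. Interpolated values never leave
#' `[min(src), max(src)]`.
#'
#' @param src A `dose_grid`.
#' @param dst_geometry Destination geometry (see [make_geometry()]).
#' @return A `dose_grid` on the destination geometry.
#' @export
resample_grid <- function(src, dst_geometry) {
  g <- grid_geometry(dst_geometry)
  if (same_geometry(src, g)) {
    return(dose_grid(src$values, g$origin, g$spacing, require_nonneg = FALSE))
  }
  ax_s <- axis_coords(src)
  ax_d <- axis_coords(g)
  vals <- trilinear_eval(src$values, ax_s, ax_d$x, ax_d$y, ax_d$z,
                         expand = TRUE)
  dose_grid(vals, g$origin, g$spacing, require_nonneg = FALSE)
}

# Trilinear interpolation of `arr` sampled at axis coordinates `ax` onto the
# tensor grid xq x yq x zq (expand = TRUE) or at point triples (expand = FALSE).
# Outside the source support the value is 0.
trilinear_eval <- function(arr, ax, xq, yq, zq, expand = FALSE) {
  d <- dim(arr)
  if (expand) {
    nx <- length(xq); ny <- length(yq); nz <- length(zq)
    X <- rep(xq, times = ny * nz)
    Y <- rep(rep(yq, each = nx), times = nz)
    Z <- rep(zq, each = nx * ny)
  } else {
    X <- xq; Y <- yq; Z <- zq
  }
  # fractional index along one axis; clamped flag marks out-of-support points
  frac_index <- function(q, coords) {
    n <- length(coords)
    if (n == 1L) {
      i0 <- rep(1L, length(q)); t <- rep(0, length(q))
      inside <- abs(q - coords[1]) < 1e-9
    } else {
      i0 <- findInterval(q, coords, rightmost.closed = TRUE)
      inside <- q >= coords[1] - 1e-9 & q <= coords[n] + 1e-9
      i0 <- pmin(pmax(i0, 1L), n - 1L)
      t <- (q - coords[i0]) / (coords[i0 + 1L] - coords[i0])
      t <- pmin(pmax(t, 0), 1)
    }
    list(i0 = i0, t = t, inside = inside)
  }
  fx <- frac_index(X, ax$x); fy <- frac_index(Y, ax$y); fz <- frac_index(Z, ax$z)
  ix1 <- pmin(fx$i0 + (if (d[1] > 1L) 1L else 0L), d[1])
  iy1 <- pmin(fy$i0 + (if (d[2] > 1L) 1L else 0L), d[2])
  iz1 <- pmin(fz$i0 + (if (d[3] > 1L) 1L else 0L), d[3])
  at <- function(i, j, k) arr[cbind(i, j, k)]
  tx <- fx$t; ty <- fy$t; tz <- fz$t
  v <-
    at(fx$i0, fy$i0, fz$i0) * (1 - tx) * (1 - ty) * (1 - tz) +
    at(ix1,   fy$i0, fz$i0) * tx       * (1 - ty) * (1 - tz) +
    at(fx$i0, iy1,   fz$i0) * (1 - tx) * ty       * (1 - tz) +
    at(ix1,   iy1,   fz$i0) * tx       * ty       * (1 - tz) +
    at(fx$i0, fy$i0, iz1)   * (1 - tx) * (1 - ty) * tz       +
    at(ix1,   fy$i0, iz1)   * tx       * (1 - ty) * tz       +
    at(fx$i0, iy1,   iz1)   * (1 - tx) * ty       * tz       +
    at(ix1,   iy1,   iz1)   * tx       * ty       * tz
  v[!(fx$inside & fy$inside & fz$inside)] <- 0
  if (expand) {
    array(v, dim = c(length(xq), length(yq), length(zq)))
  } else {
    v
  }
}
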