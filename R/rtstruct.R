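#' Planar contours of one region of interest
#'
#' The contour representation used by DICOM RT-STRUCT: a named stack of
#' closed planar polygons, one or more per axial slice, with vertices in
#' patient mm.
#'
#' @param name ROI name (e.g. `"CPG"`, `"PTV"`).
#' @param slices List of `list(z = <mm>, xy = <n x 2 matrix of (x, y) mm>)`.
#'   Polygons are implicitly closed; an explicitly repeated first vertex is
#'   dropped. Each polygon needs at least 3 distinct vertices.
#' @return An object of class `roi_contours`, slices sorted by z.
#' @export
roi_contours <- function(name, slices) {
  slices <- lapply(slices, function(s) {
    xy <- as.matrix(s$xy)
    if (nrow(xy) >= 2 && all(abs(xy[1, ] - xy[nrow(xy), ]) < 1e-9)) {
      xy <- xy[-nrow(xy), , drop = FALSE]
    }
    if (nrow(xy) < 3) rlang::abort("each contour polygon needs >= 3 vertices.")
    list(z = as.numeric(s$z), xy = xy)
  })
  slices <- slices[order(vapply(slices, function(s) s$z, numeric(1)))]
  structure(list(name = name, slices = slices), class = "roi_contours")
}

#' @export
print.roi_contours <- function(x, ...) {
  zs <- vapply(x$slices, function(s) s$z, numeric(1))
  cat(sprintf("<roi_contours> '%s': %d polygon(s) on %d z level(s), z in [%.1f, %.1f] mm\n",
              x$name, length(x$slices), length(unique(zs)),
              min(zs), max(zs)))
  invisible(x)
}

#' Read ROIs from a DICOM RT-STRUCT file
#'
#' Returns every ROI that carries contour data, with coordinates in patient
#' mm. ROIs without contours are skipped with a warning.
#'
#' @param path Path to an RT-STRUCT file.
#' @return Named list of [roi_contours()] objects.
#' @export
read_rtstruct <- function(path) {
  ds <- read_dicom_file(path)
  ssr <- dcm_get(ds, 0x3006, 0x0020, what = "StructureSetROISequence")
  names_by_number <- list()
  for (item in ssr) {
    num <- dcm_get(item, 0x3006, 0x0022, what = "ROINumber")
    nm <- dcm_get(item, 0x3006, 0x0026, required = FALSE)
    names_by_number[[as.character(num)]] <-
      if (is.null(nm)) paste0("ROI_", num) else paste(nm, collapse = " ")
  }
  rcs <- dcm_get(ds, 0x3006, 0x0039, what = "ROIContourSequence")
  out <- list()
  for (item in rcs) {
    num <- dcm_get(item, 0x3006, 0x0084, what = "ReferencedROINumber")
    nm <- names_by_number[[as.character(num)]]
    if (is.null(nm)) nm <- paste0("ROI_", num)
    cs <- dcm_get(item, 0x3006, 0x0040, required = FALSE)
    if (is.null(cs) || length(cs) == 0) {
      rlang::warn(paste0("ROI '", nm, "' has no contour data; skipped."))
      next
    }
    slices <- list()
    for (ct in cs) {
      cd <- dcm_get(ct, 0x3006, 0x0050, required = FALSE)
      if (is.null(cd)) {
        rlang::abort(paste0("corrupt contour sequence in ROI '", nm,
                            "': item without ContourData."))
      }
      if (length(cd) %% 3 != 0 || length(cd) < 9) {
        rlang::abort(paste0("malformed ContourData in ROI '", nm, "'."))
      }
      pts <- matrix(cd, ncol = 3, byrow = TRUE)
      slices[[length(slices) + 1L]] <-
        list(z = pts[1, 3], xy = pts[, 1:2, drop = FALSE])
    }
    if (length(slices) == 0) {
      rlang::warn(paste0("ROI '", nm, "' has no contour data; skipped."))
      next
    }
    out[[nm]] <- roi_contours(nm, slices)
  }
  if (length(out) == 0) rlang::abort("RT-STRUCT contains no ROI with contours.")
  out
}

#' Write ROIs to a DICOM RT-STRUCT file
#'
#' @param rois List of [roi_contours()] objects.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_rtstruct <- function(rois, path) {
  sop_uid <- dcm_new_uid()
  ssr_items <- list()
  rc_items <- list()
  for (i in seq_along(rois)) {
    roi <- rois[[i]]
    stopifnot(inherits(roi, "roi_contours"))
    ssr_items[[i]] <- encode_dataset(list(
      el(0x3006, 0x0022, "IS", i),
      el(0x3006, 0x0026, "LO", roi$name)
    ))
    contour_items <- lapply(roi$slices, function(s) {
      pts <- cbind(s$xy, s$z)
      encode_dataset(list(
        el(0x3006, 0x0042, "CS", "CLOSED_PLANAR"),
        el(0x3006, 0x0046, "IS", nrow(pts)),
        el(0x3006, 0x0050, "DS", as.numeric(t(pts)))
      ))
    })
    rc_items[[i]] <- encode_dataset(list(
      el(0x3006, 0x0040, "SQ", contour_items),
      el(0x3006, 0x0084, "IS", i)
    ))
  }
  elements <- list(
    el(0x0008, 0x0016, "UI", UID_RTSTRUCT),
    el(0x0008, 0x0018, "UI", sop_uid),
    el(0x0008, 0x0060, "CS", "RTSTRUCT"),
    el(0x3006, 0x0002, "SH", "SYNTH"),
    el(0x3006, 0x0020, "SQ", ssr_items),
    el(0x3006, 0x0039, "SQ", rc_items)
  )
  write_dicom_file(path, UID_RTSTRUCT, sop_uid, elements)
}

# crossing-number (even-odd) point-in-polygon test, vectorized over points
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  crossings <- integer(length(px))
  xs <- poly[, 1]; ys <- poly[, 2]
  xe <- xs[c(2:n, 1)]; ye <- ys[c(2:n, 1)]
  for (k in seq_len(n)) {
    y1 <- ys[k]; y2 <- ye[k]
    if (y1 == y2) next
    straddles <- (y1 > py) != (y2 > py)
    if (!any(straddles)) next
    xint <- xs[k] + (py - y1) * (xe[k] - xs[k]) / (y2 - y1)
    crossings <- crossings + as.integer(straddles & (px < xint))
  }
  crossings %% 2L == 1L
}

#' Rasterize planar contours onto a grid geometry
#'
#' A voxel is set iff its center lies inside the slice polygon(s) by the
#' even-odd rule, using the contour slice nearest to the voxel's z plane
#' (within half the contour slice gap). Multiple polygons on one slice
#' combine by even-odd parity, so holes and rings behave as in a TPS.
#'
#' @param roi A [roi_contours()].
#' @param geom Grid geometry (see [grid_geometry()]).
#' @return A [binary_mask()] on `geom`. If no contour slice lies within half
#'   a slice gap of any grid plane, the mask is empty and a warning is
#'   raised.
#' @export
rasterize <- function(roi, geom) {
  g <- grid_geometry(geom)
  ax <- axis_coords(g)
  zs <- vapply(roi$slices, function(s) s$z, numeric(1))
  uz <- sort(unique(zs))
  gap <- if (length(uz) > 1) stats::median(diff(uz)) else g$spacing[3]
  tol <- gap / 2 + 1e-9
  vox <- array(FALSE, dim = g$shape)
  px <- rep(ax$x, times = g$shape[2])
  py <- rep(ax$y, each = g$shape[1])
  matched <- FALSE
  for (k in seq_len(g$shape[3])) {
    dz <- abs(uz - ax$z[k])
    if (min(dz) > tol) next
    matched <- TRUE
    znear <- uz[which.min(dz)]
    inside <- rep(FALSE, length(px))
    for (s in roi$slices[zs == znear]) {
      inside <- xor(inside, points_in_polygon(px, py, s$xy))
    }
    vox[, , k] <- inside
  }
  if (!matched || !any(vox)) {
    rlang::warn(paste0("rasterization of ROI '", roi$name,
                       "' produced an empty mask (no contour slice near any grid plane)."))
  }
  binary_mask(vox, g)
}
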