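#' Read a DICOM RT-DOSE file
#'
#' Reconstructs the dose grid from Image Position (Patient), Pixel Spacing
#' and the Grid Frame Offset Vector, and applies Dose Grid Scaling so the
#' returned values are absolute dose in Gy. Only axis-aligned head-first
#' supine grids (identity orientation) with uniform frame offsets and
#' explicit-VR little-endian encoding are supported.
#'
#' @param path Path to an RT-DOSE file.
#' @return A [dose_grid()].
#' @export
read_rtdose <- function(path) {
  ds <- read_dicom_file(path)
  modality <- dcm_get(ds, 0x0008, 0x0060, required = FALSE)
  if (!is.null(modality) && !identical(toupper(modality), "RTDOSE")) {
    rlang::abort(paste0("not an RT-DOSE file (Modality = ", modality, ")."))
  }
  ncol_ <- dcm_get(ds, 0x0028, 0x0011, what = "Columns")
  nrow_ <- dcm_get(ds, 0x0028, 0x0010, what = "Rows")
  nframes <- dcm_get(ds, 0x0028, 0x0008, required = FALSE)
  if (is.null(nframes)) nframes <- 1L
  ipp <- dcm_get(ds, 0x0020, 0x0032, what = "ImagePositionPatient")
  iop <- dcm_get(ds, 0x0020, 0x0037, required = FALSE)
  if (!is.null(iop) && max(abs(iop - c(1, 0, 0, 0, 1, 0))) > 1e-6) {
    rlang::abort("oblique dose grids are not supported (orientation must be identity).")
  }
  pxs <- dcm_get(ds, 0x0028, 0x0030, what = "PixelSpacing")  # (row, col)
  offsets <- dcm_get(ds, 0x3004, 0x000C, required = FALSE)
  if (is.null(offsets)) offsets <- 0
  if (length(offsets) > 1) {
    gaps <- diff(offsets)
    if (any(gaps <= 0) || (max(gaps) - min(gaps)) > 1e-4 * max(abs(gaps))) {
      rlang::abort("non-uniform GridFrameOffsetVector: only uniform slice spacing is supported.")
    }
    dz <- mean(gaps)
  } else {
    dz <- dcm_get(ds, 0x0018, 0x0050, required = FALSE)  # SliceThickness
    if (is.null(dz) || length(dz) == 0 || dz <= 0) dz <- 1
  }
  scaling <- dcm_get(ds, 0x3004, 0x000E, required = FALSE)
  if (is.null(scaling)) scaling <- 1
  bits <- dcm_get(ds, 0x0028, 0x0100, required = FALSE)
  if (is.null(bits)) bits <- 32L
  pix <- dcm_get(ds, 0x7FE0, 0x0010, what = "PixelData")
  n <- as.integer(ncol_) * as.integer(nrow_) * as.integer(nframes)
  if (bits == 32L) {
    ints <- readBin(pix, "integer", n = n, size = 4, endian = "little")
    ints <- as.numeric(ints)
    ints[ints < 0] <- ints[ints < 0] + 4294967296
  } else if (bits == 16L) {
    ints <- readBin(pix, "integer", n = n, size = 2, signed = FALSE,
                    endian = "little")
    ints <- as.numeric(ints)
  } else {
    rlang::abort(paste0("unsupported BitsAllocated: ", bits))
  }
  if (length(ints) < n) rlang::abort("PixelData shorter than Rows*Columns*Frames.")
  # PixelData is column-fastest within a row-major frame: index order (x, y, z)
  vals <- array(ints[seq_len(n)] * scaling,
                dim = c(as.integer(ncol_), as.integer(nrow_), as.integer(nframes)))
  origin <- c(ipp[1], ipp[2], ipp[3] + offsets[1])
  dose_grid(vals, origin, c(pxs[2], pxs[1], dz))
}

#' Write a dose grid as DICOM RT-DOSE
#'
#' Dose is stored as 32-bit unsigned integers with a per-file Dose Grid
#' Scaling chosen so the maximum dose uses the full usable integer range;
#' the round-trip error through [read_rtdose()] is bounded by one
#' quantization step, `max(dose) / (2^31 - 1)`.
#'
#' @param grid A [dose_grid()] with non-negative values.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_rtdose <- function(grid, path) {
  stopifnot(inherits(grid, "dose_grid"))
  if (any(grid$values < 0)) rlang::abort("dose values must be non-negative.")
  d <- dim(grid$values)
  dmax <- max(grid$values)
  scaling <- if (dmax > 0) dmax / (2^31 - 1) else 1
  ints <- as.integer(round(grid$values / scaling))
  pix <- writeBin(ints, raw(), size = 4, endian = "little")
  sop_uid <- dcm_new_uid()
  elements <- list(
    el(0x0008, 0x0016, "UI", UID_RTDOSE),
    el(0x0008, 0x0018, "UI", sop_uid),
    el(0x0008, 0x0060, "CS", "RTDOSE"),
    el(0x0020, 0x0032, "DS", grid$origin),
    el(0x0020, 0x0037, "DS", c(1, 0, 0, 0, 1, 0)),
    el(0x0028, 0x0002, "US", 1L),
    el(0x0028, 0x0004, "CS", "MONOCHROME2"),
    el(0x0028, 0x0008, "IS", d[3]),
    el(0x0028, 0x0010, "US", d[2]),
    el(0x0028, 0x0011, "US", d[1]),
    el(0x0028, 0x0030, "DS", c(grid$spacing[2], grid$spacing[1])),
    el(0x0028, 0x0100, "US", 32L),
    el(0x0028, 0x0101, "US", 32L),
    el(0x0028, 0x0102, "US", 31L),
    el(0x0028, 0x0103, "US", 0L),
    el(0x3004, 0x0002, "CS", "GY"),
    el(0x3004, 0x0004, "CS", "PHYSICAL"),
    el(0x3004, 0x000A, "CS", "PLAN"),
    el(0x3004, 0x000C, "DS", (seq_len(d[3]) - 1) * grid$spacing[3]),
    el(0x3004, 0x000E, "DS", scaling),
    el(0x7FE0, 0x0010, "OW", pix)
  )
  write_dicom_file(path, UID_RTDOSE, sop_uid, elements)
}
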