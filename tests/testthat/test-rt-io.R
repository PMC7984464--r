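test_that("RT-DOSE round trip is exact to within one quantization step", {
  zero <- dose_grid(array(0, dim = c(4, 3, 2)), c(0, 0, 0), c(1, 1, 1))
  f <- withr::local_tempfile(fileext = ".dcm")
  write_rtdose(zero, f)
  expect_identical(read_rtdose(f)$values, zero$values)

  withr::with_seed(42, {
    for (i in 1:5) {
      g <- random_grid(shape = c(9, 7, 5), max_dose = stats::runif(1, 1, 90))
      write_rtdose(g, f)
      back <- read_rtdose(f)
      expect_identical(dim(back$values), dim(g$values))
      expect_equal(back$origin, g$origin, tolerance = 1e-9)
      expect_equal(back$spacing, g$spacing, tolerance = 1e-9)
      expect_lt(max(abs(back$values - g$values)), max(g$values) / 2^31)
    }
  })
})

test_that("dose grid scaling is applied: stored integer 3000 at scaling 0.001 reads as 3 Gy", {
  pix <- writeBin(rep(3000L, 6), raw(), size = 4, endian = "little")
  f <- withr::local_tempfile(fileext = ".dcm")
  elements <- list(
    parotidbp:::el(0x0008, 0x0060, "CS", "RTDOSE"),
    parotidbp:::el(0x0020, 0x0032, "DS", c(0, 0, 0)),
    parotidbp:::el(0x0028, 0x0008, "IS", 2L),
    parotidbp:::el(0x0028, 0x0010, "US", 3L),
    parotidbp:::el(0x0028, 0x0011, "US", 1L),
    parotidbp:::el(0x0028, 0x0030, "DS", c(2, 2)),
    parotidbp:::el(0x0028, 0x0100, "US", 32L),
    parotidbp:::el(0x3004, 0x000C, "DS", c(0, 2)),
    parotidbp:::el(0x3004, 0x000E, "DS", 0.001),
    parotidbp:::el(0x7FE0, 0x0010, "OW", pix)
  )
  parotidbp:::write_dicom_file(f, parotidbp:::UID_RTDOSE, "2.25.1", elements)
  g <- read_rtdose(f)
  expect_equal(as.vector(g$values), rep(3, 6))
})

test_that("non-uniform frame offsets are rejected", {
  g <- dose_grid(array(1, dim = c(2, 2, 3)), c(0, 0, 0), c(1, 1, 1))
  f <- withr::local_tempfile(fileext = ".dcm")
  write_rtdose(g, f)
  # patch the GridFrameOffsetVector to a non-uniform sequence
  bytes <- readBin(f, "raw", n = file.size(f))
  pat <- charToRaw("0\\1\\2")
  hit <- NULL
  for (i in seq_len(length(bytes) - length(pat))) {
    if (identical(bytes[i:(i + length(pat) - 1)], pat)) { hit <- i; break }
  }
  expect_false(is.null(hit))
  bytes[hit:(hit + length(pat) - 1)] <- charToRaw("0\\1\\7")
  writeBin(bytes, f)
  expect_error(read_rtdose(f), "uniform")
})

test_that("RT-STRUCT round trip preserves names, slices and vertices", {
  sq <- roi_contours("SQUARE", list(list(
    z = 0, xy = rbind(c(-5, -5), c(5, -5), c(5, 5), c(-5, 5))
  )))
  f <- withr::local_tempfile(fileext = ".dcm")
  write_rtstruct(list(sq), f)
  rois <- read_rtstruct(f)
  expect_named(rois, "SQUARE")
  expect_length(rois$SQUARE$slices, 1)
  expect_equal(nrow(rois$SQUARE$slices[[1]]$xy), 4)
  expect_equal(rois$SQUARE$slices[[1]]$xy, sq$slices[[1]]$xy,
               ignore_attr = TRUE)

  ph <- clean_phantom()
  write_rtstruct(ph$structures, f)
  rois <- read_rtstruct(f)
  expect_setequal(names(rois), c("CPG", "PTV"))
  geom <- grid_geometry(ph$clinical_dose)
  cpg <- rasterize(rois$CPG, geom)
  analytic_cc <- 4 / 3 * pi * prod(ph$config$cpg_semiaxes) / 1000
  expect_lt(abs(mask_volume_cc(cpg) - analytic_cc) / analytic_cc, 0.02)
})

test_that("an ROI without contours is skipped with a warning", {
  sq <- roi_contours("KEEP", list(list(
    z = 0, xy = rbind(c(0, 0), c(4, 0), c(4, 4))
  )))
  f <- withr::local_tempfile(fileext = ".dcm")
  # hand-build a file whose second ROI has no contour sequence
  ssr <- list(
    parotidbp:::encode_dataset(list(parotidbp:::el(0x3006, 0x0022, "IS", 1L),
                                    parotidbp:::el(0x3006, 0x0026, "LO", "KEEP"))),
    parotidbp:::encode_dataset(list(parotidbp:::el(0x3006, 0x0022, "IS", 2L),
                                    parotidbp:::el(0x3006, 0x0026, "LO", "EMPTY")))
  )
  contour_items <- list(parotidbp:::encode_dataset(list(
    parotidbp:::el(0x3006, 0x0042, "CS", "CLOSED_PLANAR"),
    parotidbp:::el(0x3006, 0x0046, "IS", 3L),
    parotidbp:::el(0x3006, 0x0050, "DS", as.numeric(t(cbind(sq$slices[[1]]$xy, 0))))
  )))
  rcs <- list(
    parotidbp:::encode_dataset(list(parotidbp:::el(0x3006, 0x0040, "SQ", contour_items),
                                    parotidbp:::el(0x3006, 0x0084, "IS", 1L))),
    parotidbp:::encode_dataset(list(parotidbp:::el(0x3006, 0x0084, "IS", 2L)))
  )
  elements <- list(
    parotidbp:::el(0x0008, 0x0060, "CS", "RTSTRUCT"),
    parotidbp:::el(0x3006, 0x0020, "SQ", ssr),
    parotidbp:::el(0x3006, 0x0039, "SQ", rcs)
  )
  parotidbp:::write_dicom_file(f, parotidbp:::UID_RTSTRUCT, "2.25.2", elements)
  expect_warning(rois <- read_rtstruct(f), "EMPTY")
  expect_named(rois, "KEEP")
})

test_that("files we write are readable by an independent DICOM implementation", {
  ph <- clean_phantom()
  fd <- withr::local_tempfile(fileext = ".dcm")
  fs <- withr::local_tempfile(fileext = ".dcm")
  out <- withr::local_tempfile(fileext = ".json")
  write_rtdose(ph$clinical_dose, fd)
  write_rtstruct(ph$structures, fs)
  script <- withr::local_tempfile(fileext = ".py")
  writeLines(c(
    "import sys, json, pydicom, numpy as np",
    "dd = pydicom.dcmread(sys.argv[1]); ss = pydicom.dcmread(sys.argv[2])",
    "arr = dd.pixel_array.astype('float64') * float(dd.DoseGridScaling)",
    "json.dump({'sum': float(arr.sum()), 'max': float(arr.max()),",
    "  'shape': list(arr.shape),",
    "  'rois': [r.ROIName for r in ss.StructureSetROISequence],",
    "  'ncontours': [len(r.ContourSequence) for r in ss.ROIContourSequence]},",
    "  open(sys.argv[3], 'w'))"
  ), script)
  status <- system2("python", c(script, fd, fs, out))
  expect_identical(status, 0L)
  res <- jsonlite::fromJSON(out)
  expect_equal(res$sum, sum(ph$clinical_dose$values), tolerance = 1e-6)
  expect_equal(res$max, max(ph$clinical_dose$values), tolerance = 1e-6)
  expect_identical(res$shape, rev(dim(ph$clinical_dose$values)))
  expect_setequal(res$rois, c("CPG", "PTV"))
  expect_true(all(res$ncontours > 10))
})

test_that("rasterization follows the even-odd voxel-center rule", {
  # 10 x 10 mm square centered on a 1 mm grid: exactly 100 centers inside
  geom <- make_geometry(c(-9.5, -9.5, 0), c(1, 1, 2), c(20, 20, 3))
  sq <- roi_contours("SQ", lapply(c(0, 2, 4), function(z) {
    list(z = z, xy = rbind(c(-5, -5), c(5, -5), c(5, 5), c(-5, 5)))
  }))
  m <- rasterize(sq, geom)
  expect_identical(apply(m$voxels, 3, sum), rep(100L, 3))

  # circle r = 20 mm on a 0.5 mm grid: area error below 1%
  th <- seq(0, 2 * pi, length.out = 181)[-181]
  circ <- roi_contours("CIRC", list(list(z = 0, xy = cbind(20 * cos(th), 20 * sin(th)))))
  geom2 <- make_geometry(c(-24.75, -24.75, 0), c(0.5, 0.5, 1), c(100, 100, 1))
  m2 <- rasterize(circ, geom2)
  area <- sum(m2$voxels) * 0.25
  expect_lt(abs(area - pi * 400) / (pi * 400), 0.01)

  # mask volume converges toward the analytic area as spacing shrinks
  geom1 <- make_geometry(c(-24.5, -24.5, 0), c(1, 1, 1), c(50, 50, 1))
  a1 <- sum(rasterize(circ, geom1)$voxels) * 1
  expect_lte(abs(area - pi * 400), abs(a1 - pi * 400) + 1e-9)
})

test_that("a polygon falling between grid slices yields an empty mask with a warning", {
  tri <- roi_contours("TRI", list(
    list(z = 1, xy = rbind(c(0, 0), c(4, 0), c(0, 4))),
    list(z = 2, xy = rbind(c(0, 0), c(4, 0), c(0, 4)))
  ))
  geom <- make_geometry(c(-1, -1, -0.5), c(1, 1, 4), c(8, 8, 2))  # slices at -0.5, 3.5
  expect_warning(m <- rasterize(tri, geom), "empty")
  expect_false(any(m$voxels))
})
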