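# Shared fixtures, built once per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# a rectangular box mask with exactly nx*ny*nz voxels inside a padded grid
box_mask <- function(nx, ny, nz, spacing = c(1, 1, 1), pad = 1L) {
  shape <- c(nx, ny, nz) + 2L * pad
  vox <- array(FALSE, dim = shape)
  vox[pad + seq_len(nx), pad + seq_len(ny), pad + seq_len(nz)] <- TRUE
  binary_mask(vox, make_geometry(c(0, 0, 0), spacing, shape))
}

# ellipsoid mask built directly from voxel-center membership
ellipsoid_mask <- function(semiaxes_vox, spacing = c(1, 1, 1), pad = 2L) {
  shape <- as.integer(2 * ceiling(semiaxes_vox) + 1L + 2L * pad)
  ctr_idx <- (shape + 1) / 2
  geom <- make_geometry(c(0, 0, 0), spacing, shape)
  f <- function(i, s, c0) ((i - c0) / s)^2
  ax <- list(x = seq_len(shape[1]), y = seq_len(shape[2]), z = seq_len(shape[3]))
  arr <- outer(outer(f(ax$x, semiaxes_vox[1], ctr_idx[1]),
                     f(ax$y, semiaxes_vox[2], ctr_idx[2]), "+"),
               f(ax$z, semiaxes_vox[3], ctr_idx[3]), "+")
  binary_mask(arr <= 1, geom)
}

random_grid <- function(shape = c(6, 5, 4), max_dose = 70) {
  vals <- array(stats::runif(prod(shape), 0, max_dose), dim = shape)
  dose_grid(vals, c(-10, -5, 0), c(2, 2.5, 3))
}

# default phantom (the standard study conditions) - built once
default_phantom <- function() fixture("phantom_default", function() {
  make_phantom(phantom_config())
})
default_masks <- function() fixture("masks_default", function() {
  phantom_masks(default_phantom())
})
default_ranked <- function() fixture("ranked_default", function() {
  assign_ranks(partition_equal_volume(default_masks()$CPG),
               importance_table_synthetic(), "right")
})

# zero-overlap, noise-free phantom for exact base-plan arithmetic
clean_phantom <- function() fixture("phantom_clean", function() {
  make_phantom(phantom_config(overlap_fraction_target = 0, noise_sd = 0))
})
clean_masks <- function() fixture("masks_clean", function() {
  phantom_masks(clean_phantom())
})
clean_ranked <- function() fixture("ranked_clean", function() {
  assign_ranks(partition_equal_volume(clean_masks()$CPG),
               importance_table_synthetic(), "right")
})

empty_mask_like <- function(mask) {
  binary_mask(array(FALSE, dim = dim(mask$voxels)), mask$grid)
}

# small, fast phantom + influence matrix for optimizer tests
opt_fixture <- function() fixture("opt_fixture", function() {
  ph <- make_phantom(phantom_config(grid_spacing = 4, noise_sd = 0,
                                    overlap_fraction_target = 0.13))
  masks <- phantom_masks(ph)
  infl <- build_influence(grid_geometry(ph$clinical_dose), masks$PTV,
                          n_angles = 7, beamlet_width = 6)
  ranked <- assign_ranks(partition_equal_volume(masks$CPG),
                         importance_table_synthetic(), "right")
  list(phantom = ph, masks = masks, infl = infl, ranked = ranked)
})
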