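#' Configuration for a synthetic head-and-neck phantom
#'
#' Defaults emulate a typical head-and-neck planning case: an ellipsoidal
#' contralateral parotid gland (CPG) of about 30 cc, a spherical primary PTV
#' of 181.5 cc (the cohort median of the planning study this mimics), a
#' prescription of 70 Gy, and a 2.5 mm isotropic dose grid. With
#' `overlap_fraction_target = 0` the PTV is placed with a 33 mm surface gap
#' to the gland, matching the typical PTV-to-CPG minimum distance of 3.3 cm.
#' The default overlap target of 0.13 matches the typical (median) CPG-PTV
#' overlap of about 13%.
#'
#' @param cpg_semiaxes Ellipsoid semi-axes (x, y, z) in mm.
#' @param cpg_center Ellipsoid center in patient mm (right parotid: x < 0).
#' @param ptv_volume_target PTV volume in cc (sphere).
#' @param overlap_fraction_target Fraction of the CPG volume inside the PTV,
#'   in `[0, 0.35]`.
#' @param prescription Prescription dose in Gy.
#' @param grid_spacing Isotropic dose-grid spacing in mm.
#' @param noise_sd Gaussian noise added to the clinical dose (Gy, truncated
#'   at 0); 0 disables noise.
#' @param laterality `"right"` or `"left"` parotid.
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(cpg_semiaxes = c(14.5, 19, 26),
                           cpg_center = c(-45, -15, 0),
                           ptv_volume_target = 181.5,
                           overlap_fraction_target = 0.13,
                           prescription = 70,
                           grid_spacing = 2.5,
                           noise_sd = 0.5,
                           laterality = "right",
                           seed = 0L) {
  if (overlap_fraction_target < 0 || overlap_fraction_target > 0.35) {
    rlang::abort("`overlap_fraction_target` must lie in [0, 0.35].")
  }
  if (prescription <= 0) rlang::abort("`prescription` must be positive.")
  if (grid_spacing <= 0) rlang::abort("`grid_spacing` must be positive.")
  laterality <- match.arg(laterality, c("right", "left"))
  structure(list(
    cpg_semiaxes = as.numeric(cpg_semiaxes),
    cpg_center = as.numeric(cpg_center),
    ptv_volume_target = ptv_volume_target,
    overlap_fraction_target = overlap_fraction_target,
    prescription = prescription,
    grid_spacing = grid_spacing,
    noise_sd = noise_sd,
    laterality = laterality,
    seed = as.integer(seed)
  ), class = "phantom_config")
}

#' Read a phantom configuration from JSON
#'
#' The JSON object may carry any subset of the [phantom_config()] fields;
#' missing fields take the defaults and unknown fields are an error.
#'
#' @param path JSON file path.
#' @return A `phantom_config`.
#' @export
read_phantom_config <- function(path) {
  raw <- jsonlite::fromJSON(path)
  known <- names(formals(phantom_config))
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    rlang::abort(paste0("unknown phantom config fields: ",
                        paste(extra, collapse = ", ")))
  }
  do.call(phantom_config, raw)
}

# run code with a locally-seeded RNG, restoring the caller's RNG state
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# ellipsoid support radius along unit direction u
ellipsoid_radius_along <- function(semiaxes, u) {
  1 / sqrt(sum((u / semiaxes)^2))
}

# analytic membership of grid voxel centers, returned as logical array
ellipsoid_membership <- function(geom, center, semiaxes) {
  ax <- axis_coords(geom)
  fx <- ((ax$x - center[1]) / semiaxes[1])^2
  fy <- ((ax$y - center[2]) / semiaxes[2])^2
  fz <- ((ax$z - center[3]) / semiaxes[3])^2
  arr <- outer(outer(fx, fy, "+"), fz, "+")
  arr <= 1
}

ellipse_polygon <- function(center_xy, a, b, n = 72) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(center_xy[1] + a * cos(th), center_xy[2] + b * sin(th))
}

# contour an axis-aligned ellipsoid on the grid's z planes
contour_ellipsoid <- function(name, geom, center, semiaxes, n_vertices = 72) {
  ax <- axis_coords(geom)
  slices <- list()
  for (z in ax$z) {
    t <- (z - center[3]) / semiaxes[3]
    if (abs(t) >= 1) next
    scale <- sqrt(1 - t^2)
    if (scale * min(semiaxes[1:2]) < 0.3) next  # skip sub-voxel pole caps
    slices[[length(slices) + 1L]] <- list(
      z = z,
      xy = ellipse_polygon(center[1:2], semiaxes[1] * scale,
                           semiaxes[2] * scale, n_vertices)
    )
  }
  roi_contours(name, slices)
}

#' Generate a synthetic head-and-neck phantom
#'
#' Builds per-slice contours for an ellipsoidal CPG and a spherical PTV,
#' placing the PTV (toward medial/caudal) so the rasterized CPG-PTV overlap
#' fraction hits the configured target within about 2 percentage points,
#' and synthesizes a clinical-like dose: the prescription inside the PTV
#' with exponential falloff `exp(-d / 12 mm)` outside, plus optional
#' truncated Gaussian noise. Output is reproducible: the same config (and
#' seed) gives identical structures and dose.
#'
#' @param config A [phantom_config()].
#' @return An object of class `hn_phantom`: a list with `structures` (named
#'   list of [roi_contours()]: `CPG`, `PTV`), `clinical_dose` (a
#'   [dose_grid()]), and `config`.
#' @export
make_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  semi <- config$cpg_semiaxes
  ctr <- config$cpg_center
  r_ptv <- (3 * config$ptv_volume_target * 1000 / (4 * pi))^(1 / 3)
  # placement direction: medial, slightly posterior, caudal
  u <- c(if (ctr[1] <= 0) 1 else -1, 0.4, -0.6)
  u <- u / sqrt(sum(u^2))
  r_cpg_u <- ellipsoid_radius_along(semi, u)

  d_touch <- r_ptv + r_cpg_u
  d_far <- d_touch + 33          # zero-overlap placement: 3.3 cm surface gap
  margin <- 18
  sp <- rep(config$grid_spacing, 3)
  # grid covers the gland and the farthest possible PTV placement
  corners <- rbind(
    ctr - semi, ctr + semi,
    ctr + d_far * u - r_ptv, ctr + d_far * u + r_ptv,
    ctr + 0.4 * d_touch * u - r_ptv, ctr + 0.4 * d_touch * u + r_ptv
  )
  lo <- apply(corners, 2, min) - margin
  hi <- apply(corners, 2, max) + margin
  shape <- pmax(2L, as.integer(ceiling((hi - lo) / sp)) + 1L)
  geom <- make_geometry(lo, sp, shape)

  cpg_in <- ellipsoid_membership(geom, ctr, semi)
  n_cpg <- sum(cpg_in)
  if (n_cpg == 0) rlang::abort("CPG does not intersect the phantom grid.")
  overlap_at <- function(d) {
    ptv_in <- ellipsoid_membership(geom, ctr + d * u, rep(r_ptv, 3))
    sum(ptv_in & cpg_in) / n_cpg
  }
  target <- config$overlap_fraction_target
  if (target == 0) {
    d_ptv <- d_far
  } else {
    lo_d <- 0; hi_d <- d_touch
    if (overlap_at(lo_d) < target) {
      rlang::abort("infeasible overlap target: PTV cannot cover that much of the CPG.")
    }
    for (i in 1:30) {
      mid <- (lo_d + hi_d) / 2
      if (overlap_at(mid) >= target) lo_d <- mid else hi_d <- mid
    }
    d_ptv <- lo_d
    achieved <- overlap_at(d_ptv)
    if (abs(achieved - target) > 0.02) {
      rlang::abort(sprintf(
        "infeasible overlap target: best achievable %.3f vs requested %.3f.",
        achieved, target))
    }
  }
  ptv_ctr <- ctr + d_ptv * u

  structures <- list(
    CPG = contour_ellipsoid("CPG", geom, ctr, semi),
    PTV = contour_ellipsoid("PTV", geom, ptv_ctr, rep(r_ptv, 3))
  )

  ptv_mask <- suppressWarnings(rasterize(structures$PTV, geom))
  dist_mm <- distance_to_mask(ptv_mask)
  falloff <- 12  # mm; clinical-like lateral/longitudinal dose gradient
  vals <- config$prescription * exp(-dist_mm / falloff)
  vals[ptv_mask$voxels] <- config$prescription
  if (config$noise_sd > 0) {
    vals <- with_local_seed(config$seed, {
      pmax(0, vals + stats::rnorm(length(vals), sd = config$noise_sd))
    })
    vals <- array(vals, dim = grid_geometry(geom)$shape)
  }
  structure(list(
    structures = structures,
    clinical_dose = dose_grid(vals, geom$origin, geom$spacing),
    config = config,
    ptv_center = ptv_ctr
  ), class = "hn_phantom")
}

#' @export
print.hn_phantom <- function(x, ...) {
  cat(sprintf(
    "<hn_phantom> CPG semiaxes (%.1f, %.1f, %.1f) mm, overlap target %.2f, Rx %.0f Gy\n",
    x$config$cpg_semiaxes[1], x$config$cpg_semiaxes[2], x$config$cpg_semiaxes[3],
    x$config$overlap_fraction_target, x$config$prescription))
  print(x$clinical_dose)
  invisible(x)
}

#' Rasterize a phantom's structures onto its dose grid
#'
#' @param phantom An `hn_phantom`.
#' @return List of [binary_mask()]s named like the structures.
#' @export
phantom_masks <- function(phantom) {
  geom <- grid_geometry(phantom$clinical_dose)
  lapply(phantom$structures, rasterize, geom = geom)
}

#' Generate a cohort of jittered phantoms
#'
#' Mirrors a multi-patient planning study: each phantom gets CPG semi-axes
#' jittered by up to ±20% and an overlap fraction drawn uniformly from
#' `[0, 0.33]` (the typical observed range, whose maximum is 33%).
#' Deterministic under `seed`.
#'
#' @param n Number of phantoms (>= 2).
#' @param base_config A [phantom_config()] used as the template.
#' @param seed Integer seed for the jitter (and, derived, each phantom).
#' @param jitter Relative semi-axis jitter amplitude (default 0.2; 0 gives
#'   identical phantoms).
#' @return List of `hn_phantom` objects.
#' @export
make_cohort <- function(n, base_config = phantom_config(), seed = 1L,
                        jitter = 0.2) {
  if (n < 2) rlang::abort("a cohort needs at least 2 phantoms.")
  draws <- with_local_seed(seed, {
    list(
      scale = matrix(stats::runif(3 * n, 1 - jitter, 1 + jitter), nrow = n),
      overlap = if (jitter > 0) stats::runif(n, 0, 0.33)
                else rep(base_config$overlap_fraction_target, n)
    )
  })
  lapply(seq_len(n), function(i) {
    cfg <- base_config
    cfg$cpg_semiaxes <- base_config$cpg_semiaxes * draws$scale[i, ]
    cfg$overlap_fraction_target <- draws$overlap[i]
    cfg$seed <- if (jitter > 0) {
      as.integer((seed * 1000 + i) %% .Machine$integer.max)
    } else {
      base_config$seed
    }
    make_phantom(cfg)
  })
}
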