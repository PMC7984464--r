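test_that("beamlet dose attenuates monotonically with depth along the beam axis", {
  # single anterior beam (gantry 0 enters at low y) on a slab geometry
  geom <- make_geometry(c(0, 0, 0), c(2, 2, 2), c(15, 30, 9))
  ptv <- array(FALSE, dim = c(15, 30, 9)); ptv[6:10, 13:18, 4:6] <- TRUE
  infl <- build_influence(geom, binary_mask(ptv, geom), n_angles = 3,
                          beamlet_width = 6)
  bl <- infl$beamlets[infl$beamlets$gantry_deg == 0, ]
  bl <- bl[order(abs(bl$u_offset), abs(bl$z_offset - 9)), ]
  b0 <- bl$beamlet[1]
  dose <- array(as.numeric(infl$A[, b0]), dim = c(15, 30, 9))
  ray <- dose[8, , 5]  # along +y = along the beam
  on_axis <- which(ray > 0)
  expect_gt(length(on_axis), 10)
  expect_true(all(diff(ray[on_axis]) < 0))
})

test_that("opposed beams of a symmetric geometry deposit mirrored dose", {
  geom <- make_geometry(c(0, 0, 0), c(2, 2, 2), c(15, 31, 9))
  ptv <- array(FALSE, dim = c(15, 31, 9)); ptv[6:10, 14:18, 4:6] <- TRUE
  infl <- build_influence(geom, binary_mask(ptv, geom), n_angles = 4,
                          beamlet_width = 6)
  pick <- function(angle) {
    bl <- infl$beamlets[infl$beamlets$gantry_deg == angle, ]
    bl <- bl[order(abs(bl$u_offset), abs(bl$z_offset - 9)), ]
    bl$beamlet[1]
  }
  b_ant <- pick(0)
  b_post <- pick(180)
  d_ant <- array(as.numeric(infl$A[, b_ant]), dim = c(15, 31, 9))
  d_post <- array(as.numeric(infl$A[, b_post]), dim = c(15, 31, 9))
  expect_equal(d_ant[8, , 5], rev(d_post[8, , 5]), tolerance = 1e-9)
})

test_that("every PTV voxel is covered or the build aborts", {
  f <- opt_fixture()
  covered <- Matrix::rowSums(f$infl$A[which(f$masks$PTV$voxels), ]) > 0
  expect_true(all(covered))
  geom <- grid_geometry(f$phantom$clinical_dose)
  expect_error(build_influence(geom, f$masks$PTV, n_angles = 2), "at least 3")
})

test_that("a zero prescription yields zero fluence and zero dose", {
  f <- opt_fixture()
  obj <- plan_objectives(f$masks$PTV, f$masks$CPG, prescription = 0)
  plan <- optimize_fluence(f$infl, obj, iterations = 5)
  expect_identical(unique(plan$fluence), 0)
  expect_identical(unique(as.vector(plan$dose$values)), 0)
})

test_that("uniformly rescaling all penalty weights leaves the optimum unchanged", {
  f <- opt_fixture()
  rx <- f$phantom$config$prescription
  o1 <- plan_objectives(f$masks$PTV, f$masks$CPG, rx,
                        ptv_weight = 1, mean_weight = 0.5, dmax_weight = 0.5,
                        mean_bound = 20)
  o2 <- plan_objectives(f$masks$PTV, f$masks$CPG, rx,
                        ptv_weight = 2, mean_weight = 1, dmax_weight = 1,
                        mean_bound = 20)
  p1 <- optimize_fluence(f$infl, o1, iterations = 60)
  p2 <- optimize_fluence(f$infl, o2, iterations = 60)
  expect_equal(p1$fluence, p2$fluence, tolerance = 1e-9)
  expect_error(plan_objectives(f$masks$PTV, f$masks$CPG, rx, ptv_weight = -1),
               "non-negative")
  expect_error(plan_objectives(f$masks$PTV, f$masks$CPG, rx, ptv_weight = 0,
                               mean_weight = 0, dmax_weight = 0),
               "positive")
})

test_that("the line search keeps the objective non-increasing", {
  f <- opt_fixture()
  rx <- f$phantom$config$prescription
  obj <- plan_objectives(f$masks$PTV, f$masks$CPG, rx, mean_bound = 20)
  plan <- optimize_fluence(f$infl, obj, iterations = 120)
  expect_true(all(diff(plan$objective_trace) <= 1e-12))
  expect_lt(plan$objective, plan$objective_trace[1])
  # and it actually covers the target
  expect_gt(v98(plan$dose, f$masks$PTV, rx), 0.95)
})

test_that("loading a uniform base plan is identical to lowering the bounds", {
  # on a zero-overlap phantom, a base plan that is constant c on the whole
  # CPG shifts both penalty terms by exactly c, so optimizing with the base
  # plan at bounds (m + c, x + c) equals optimizing without it at (m, x)
  f <- fixture("opt_clean", function() {
    ph <- make_phantom(phantom_config(grid_spacing = 4, noise_sd = 0,
                                      overlap_fraction_target = 0))
    masks <- phantom_masks(ph)
    infl <- build_influence(grid_geometry(ph$clinical_dose), masks$PTV,
                            n_angles = 7, beamlet_width = 6)
    list(ph = ph, masks = masks, infl = infl)
  })
  rx <- f$ph$config$prescription
  cvals <- array(0, dim = dim(f$masks$CPG$voxels))
  cvals[f$masks$CPG$voxels] <- 12
  g <- f$masks$CPG$grid
  const_bp <- dose_grid(cvals, g$origin, g$spacing)

  with_bp <- plan_objectives(f$masks$PTV, f$masks$CPG, rx,
                             mean_bound = 20 + 12, dmax_bound = 40 + 12,
                             base_plan = const_bp)
  without <- plan_objectives(f$masks$PTV, f$masks$CPG, rx,
                             mean_bound = 20, dmax_bound = 40)
  p_with <- optimize_fluence(f$infl, with_bp, iterations = 80)
  p_without <- optimize_fluence(f$infl, without, iterations = 80)
  expect_equal(p_with$fluence, p_without$fluence, tolerance = 1e-9)
})

test_that("a loaded base plan steers dose off the important subsegments at matched coverage", {
  cmp <- fixture("cmp_top5", function() {
    f <- opt_fixture()
    matched_coverage_pair(f$phantom, make_variant_suite()$BP_top5,
                          infl = f$infl, iterations = 300)
  })
  s <- cmp$summary
  expect_lt(abs(s$v98_bp - s$v98_control), 0.005 + 1e-12)
  expect_lt(s$s1_mean_bp, s$s1_mean_control)       # dose steered off S1
  expect_gt(s$s_bp, s$s_control)                   # predicted saliva improves
  expect_gt(s$v98_control, 0.9)

  # mean steering across the top-5 ranks, not just S1
  td <- tidy(cmp)
  top5 <- td[td$rank <= 5, ]
  ctl5 <- mean(top5$mean_dose[top5$plan == "control"])
  bp5 <- mean(top5$mean_dose[top5$plan != "control"])
  expect_lt(bp5, ctl5)
  expect_identical(glance(cmp), s)
})
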