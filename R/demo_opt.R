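# Demonstration inverse-planning optimizer.
#
# This is explicitly a toy: parallel pencil beams with exponential depth
# attenuation and Gaussian lateral profiles, one-sided quadratic penalties,
# projected gradient descent. It exists to show the mechanism end to end on
# phantoms - that loading an artificial base plan plus one CPG upper-bound
# constraint steers dose away from high-importance subsegments at matched
# target coverage - not to emulate a clinical VMAT optimizer.

#' Build a pencil-beam influence matrix for a phantom grid
#'
#' Parallel beams at `n_angles` equispaced gantry angles in the axial
#' plane; per angle, a 2D fluence map of beamlets offset laterally (in the
#' axial plane) and in z, covering the PTV with a margin. Each beamlet
#' deposits `exp(-mu * depth)` along its axis with a Gaussian lateral
#' profile (sigma = half the beamlet width), truncated at 2.5 sigma and
#' stored sparsely.
#'
#' @param geom Grid geometry (the phantom dose grid).
#' @param ptv_mask PTV [binary_mask()] used to center and size the beamlet
#'   apertures.
#' @param n_angles Number of gantry angles (>= 3).
#' @param beamlet_width Beamlet width in mm (spacing of lateral/z offsets).
#' @param mu Effective attenuation per mm (default 0.004, a clinical-like
#'   megavoltage depth falloff).
#' @param margin Aperture margin around the PTV in mm.
#' @return An `influence_matrix`: sparse matrix `A` (voxels x beamlets),
#'   the geometry, and a tibble of beamlet geometry.
#' @export
build_influence <- function(geom, ptv_mask, n_angles = 7, beamlet_width = 6,
                            mu = 0.004, margin = 6) {
  if (n_angles < 3) rlang::abort("`n_angles` must be at least 3.")
  g <- grid_geometry(geom)
  ax <- axis_coords(g)
  nvox <- prod(g$shape)
  X <- rep(ax$x, times = g$shape[2] * g$shape[3])
  Y <- rep(rep(ax$y, each = g$shape[1]), times = g$shape[3])
  Z <- rep(ax$z, each = g$shape[1] * g$shape[2])

  pi_idx <- which(ptv_mask$voxels)
  if (length(pi_idx) == 0) rlang::abort("PTV mask is empty.")
  ctr <- c(mean(X[pi_idx]), mean(Y[pi_idx]), mean(Z[pi_idx]))
  half_u <- max(sqrt((X[pi_idx] - ctr[1])^2 + (Y[pi_idx] - ctr[2])^2)) + margin
  half_z <- max(abs(Z[pi_idx] - ctr[3])) + margin
  u_offs <- seq(-half_u, half_u, by = beamlet_width)
  z_offs <- seq(ctr[3] - half_z, ctr[3] + half_z, by = beamlet_width)
  sigma <- beamlet_width / 2
  cut <- 2.5 * sigma
  angles <- seq(0, 360, length.out = n_angles + 1)[seq_len(n_angles)]

  triplets_i <- vector("list", n_angles * length(u_offs) * length(z_offs))
  triplets_x <- triplets_i
  beam_rows <- triplets_i
  b <- 0L
  for (th_deg in angles) {
    th <- th_deg * pi / 180
    # beam axis direction in the axial plane; gantry 0 enters anteriorly
    dvec <- c(sin(th), cos(th))
    uvec <- c(cos(th), -sin(th))
    proj_t <- (X - ctr[1]) * dvec[1] + (Y - ctr[2]) * dvec[2]
    proj_u <- (X - ctr[1]) * uvec[1] + (Y - ctr[2]) * uvec[2]
    depth <- proj_t - min(proj_t)
    att <- exp(-mu * depth)
    for (uo in u_offs) {
      du <- proj_u - uo
      lat_ok <- abs(du) <= cut
      lat <- exp(-du[lat_ok]^2 / (2 * sigma^2))
      idx_lat <- which(lat_ok)
      for (zo in z_offs) {
        b <- b + 1L
        dz <- Z[idx_lat] - zo
        ok <- abs(dz) <= cut
        vals <- att[idx_lat[ok]] * lat[ok] * exp(-dz[ok]^2 / (2 * sigma^2))
        keep <- vals > 1e-6
        triplets_i[[b]] <- idx_lat[ok][keep]
        triplets_x[[b]] <- vals[keep]
        beam_rows[[b]] <- tibble::tibble(beamlet = b, gantry_deg = th_deg,
                                         u_offset = uo, z_offset = zo)
      }
    }
  }
  nb <- b
  lens <- lengths(triplets_i)
  A <- Matrix::sparseMatrix(
    i = unlist(triplets_i),
    j = rep.int(seq_len(nb), lens),
    x = unlist(triplets_x),
    dims = c(nvox, nb)
  )
  covered <- Matrix::rowSums(A[pi_idx, , drop = FALSE]) > 0
  if (!all(covered)) {
    rlang::abort("infeasible geometry: some PTV voxels receive no beamlet influence.")
  }
  structure(list(A = A, geom = g,
                 beamlets = dplyr::bind_rows(beam_rows)),
            class = "influence_matrix")
}

#' @export
print.influence_matrix <- function(x, ...) {
  cat(sprintf("<influence_matrix> %d voxels x %d beamlets, %d angles, %.0f nnz\n",
              nrow(x$A), ncol(x$A), length(unique(x$beamlets$gantry_deg)),
              Matrix::nnzero(x$A)))
  invisible(x)
}

#' Objectives for the demonstration optimizer
#'
#' One-sided quadratic penalties: underdose below the prescription on the
#' PTV, overdose above the shifted whole-mean bound and (optionally) above
#' the maximum-dose bound on the CPG. When a base plan is supplied, both
#' CPG terms are evaluated on (optimized dose + base-plan dose), mirroring
#' how a loaded base plan is absorbed by a clinical optimizer; the base
#' plan itself is artificial and is never part of the delivered dose.
#' Weights are normalized internally to sum to 1, so uniformly rescaling
#' all weights leaves the optimum unchanged.
#'
#' @param ptv_mask,cpg_mask [binary_mask()]s on the influence geometry.
#' @param prescription Prescription dose in Gy.
#' @param ptv_weight,mean_weight,dmax_weight Penalty weights (>= 0).
#' @param mean_bound CPG whole-mean bound in Gy (use the shifted bound from
#'   [constraint_set()] when a base plan is loaded).
#' @param dmax_bound CPG maximum-dose bound in Gy, or `NULL` for none.
#' @param base_plan Base-plan [dose_grid()] on the same geometry, or `NULL`.
#' @return A `plan_objectives` list.
#' @export
plan_objectives <- function(ptv_mask, cpg_mask, prescription,
                            ptv_weight = 1, mean_weight = 0.5,
                            dmax_weight = 0.5,
                            mean_bound = 20, dmax_bound = NULL,
                            base_plan = NULL) {
  w <- c(ptv_weight, mean_weight, dmax_weight)
  if (any(w < 0)) rlang::abort("weights must be non-negative.")
  if (sum(w) == 0) rlang::abort("at least one weight must be positive.")
  w <- w / sum(w)
  # the maximum-dose bound deliberately skips the CPG-PTV overlap: the base
  # plan is zeroed there so that target coverage is never penalized, and
  # capping those voxels would defeat exactly that rule
  cpg_idx <- which(cpg_mask$voxels)
  dmax_idx <- which(cpg_mask$voxels & !ptv_mask$voxels)
  structure(list(
    ptv_idx = which(ptv_mask$voxels),
    cpg_idx = cpg_idx,
    dmax_idx = dmax_idx,
    prescription = prescription,
    w_ptv = w[1], w_mean = w[2], w_dmax = w[3],
    mean_bound = mean_bound, dmax_bound = dmax_bound,
    bp_mean = if (is.null(base_plan)) 0 else base_plan$values[cpg_idx],
    bp_dmax = if (is.null(base_plan)) 0 else base_plan$values[dmax_idx]
  ), class = "plan_objectives")
}

# objective and gradient in fluence space
demo_objective <- function(w, infl, obj) {
  d <- as.numeric(infl$A %*% w)
  d_ptv <- d[obj$ptv_idx]
  under <- pmax(obj$prescription - d_ptv, 0)
  f <- obj$w_ptv * mean(under^2)
  g_vox <- numeric(length(d))
  g_vox[obj$ptv_idx] <- -2 * obj$w_ptv * under / length(obj$ptv_idx)
  mean_excess <- max(mean(d[obj$cpg_idx] + obj$bp_mean) - obj$mean_bound, 0)
  if (obj$w_mean > 0 && mean_excess > 0) {
    f <- f + obj$w_mean * mean_excess^2
    g_vox[obj$cpg_idx] <- g_vox[obj$cpg_idx] +
      2 * obj$w_mean * mean_excess / length(obj$cpg_idx)
  }
  if (obj$w_dmax > 0 && !is.null(obj$dmax_bound) && length(obj$dmax_idx)) {
    over <- pmax(d[obj$dmax_idx] + obj$bp_dmax - obj$dmax_bound, 0)
    f <- f + obj$w_dmax * mean(over^2)
    g_vox[obj$dmax_idx] <- g_vox[obj$dmax_idx] +
      2 * obj$w_dmax * over / length(obj$dmax_idx)
  }
  grad <- as.numeric(Matrix::crossprod(infl$A, g_vox))
  list(f = f, grad = grad, dose = d)
}

#' Optimize beamlet fluence against the objectives
#'
#' Projected gradient descent with backtracking line search (so the
#' objective is non-increasing across iterations) from a deterministic
#' uniform start; fluence is kept non-negative by projection. Returns the
#' final *physical* dose, which never includes the artificial base plan:
#' the base plan only shapes the CPG penalty terms.
#'
#' @param infl An `influence_matrix`.
#' @param obj A [plan_objectives()].
#' @param iterations Iteration budget (default 400).
#' @param init Initial uniform fluence value (default scaled so mean PTV
#'   dose is near the prescription).
#' @return A list of class `demo_plan`: `fluence`, `dose` ([dose_grid()]),
#'   `objective_trace`, `converged`.
#' @export
optimize_fluence <- function(infl, obj, iterations = 400, init = NULL) {
  nb <- ncol(infl$A)
  if (is.null(init)) {
    d1 <- as.numeric(infl$A %*% rep(1, nb))
    m <- mean(d1[obj$ptv_idx])
    init <- if (m > 0) obj$prescription / m else 1
  }
  if (obj$prescription <= 0) {
    # trivial optimum: nothing to cover, penalties vanish at zero fluence
    w <- rep(0, nb)
  } else {
    w <- rep(init, nb)
  }
  ev <- demo_objective(w, infl, obj)
  trace <- numeric(iterations + 1)
  trace[1] <- ev$f
  step <- 1 / max(sum(abs(ev$grad)), 1e-12)
  for (it in seq_len(iterations)) {
    gnorm2 <- sum(ev$grad^2)
    if (gnorm2 < 1e-20) {
      trace[(it + 1):(iterations + 1)] <- ev$f
      break
    }
    accepted <- FALSE
    for (bt in 1:40) {
      w_new <- pmax(w - step * ev$grad, 0)
      ev_new <- demo_objective(w_new, infl, obj)
      if (ev_new$f <= ev$f + 1e-4 * sum(ev$grad * (w_new - w)) ||
          ev_new$f < ev$f) {
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) {
      trace[(it + 1):(iterations + 1)] <- ev$f
      break
    }
    w <- w_new
    ev <- ev_new
    step <- step * 1.3
    trace[it + 1] <- ev$f
  }
  g <- infl$geom
  structure(list(
    fluence = w,
    dose = dose_grid(array(ev$dose, dim = g$shape), g$origin, g$spacing),
    objective_trace = trace,
    objective = ev$f
  ), class = "demo_plan")
}

#' @export
print.demo_plan <- function(x, ...) {
  cat(sprintf("<demo_plan> %d beamlets, final objective %.4g\n",
              length(x$fluence), x$objective))
  invisible(x)
}

#' Control vs base-plan optimization at matched target coverage
#'
#' Runs the whole demonstration for one phantom: subsegment the CPG, build
#' the requested base-plan variant and its constraint set, optimize a
#' control plan (clinical whole-mean bound only) and a base-plan plan
#' (shifted mean bound + Dmax bound, penalties evaluated on dose + base
#' plan), then bisect the base-plan run's PTV weight until the two plans'
#' PTV V98 agree within `v98_tol`. Emits metrics and saliva predictions
#' for both.
#'
#' @param phantom An `hn_phantom`.
#' @param spec A [base_plan_spec()] (e.g. one of [make_variant_suite()]).
#' @param table An [importance_table()].
#' @param hill A [hill_params()] tibble.
#' @param clinical_mean_bound Clinical CPG whole-mean bound in Gy.
#' @param dmax_margin Margin above the base-plan maximum, Gy in `[0, 15]`.
#' @param infl Optional prebuilt `influence_matrix` for this phantom.
#' @param n_angles,beamlet_width Influence-matrix resolution.
#' @param iterations Optimizer iteration budget per run.
#' @param v98_tol Coverage matching tolerance (default 0.005).
#' @param max_bisect Maximum bisection steps (default 30).
#' @return A list of class `bp_comparison`: `control` and `bp` (each with
#'   `plan`, `metrics`, `saliva`), `constraints`, `spec`, and `summary`
#'   (a one-row tibble).
#' @export
matched_coverage_pair <- function(phantom, spec, table = importance_table_synthetic(),
                                  hill = hill_params_synthetic(),
                                  clinical_mean_bound = 20, dmax_margin = 10,
                                  infl = NULL,
                                  n_angles = 7, beamlet_width = 6,
                                  iterations = 400, v98_tol = 0.005,
                                  max_bisect = 30) {
  geom <- grid_geometry(phantom$clinical_dose)
  masks <- phantom_masks(phantom)
  ranked <- assign_ranks(partition_equal_volume(masks$CPG), table,
                         phantom$config$laterality)
  I <- scaling_factors(table)
  bp <- build_base_plan(ranked, masks$PTV, spec, I)
  cons <- constraint_set(bp, masks$CPG, clinical_mean_bound, dmax_margin)
  if (is.null(infl)) {
    infl <- build_influence(geom, masks$PTV, n_angles = n_angles,
                            beamlet_width = beamlet_width)
  }
  rx <- phantom$config$prescription

  obj_control <- plan_objectives(masks$PTV, masks$CPG, rx,
                                 mean_bound = clinical_mean_bound)
  control <- optimize_fluence(infl, obj_control, iterations)
  v98_target <- v98(control$dose, masks$PTV, rx)

  run_bp <- function(ptv_weight) {
    obj_bp <- plan_objectives(masks$PTV, masks$CPG, rx,
                              ptv_weight = ptv_weight,
                              mean_bound = cons$cpg_mean_bound_shifted,
                              dmax_bound = cons$cpg_dmax_bound,
                              base_plan = bp)
    optimize_fluence(infl, obj_bp, iterations)
  }
  lo <- 1 / 64; hi <- 64
  plan_bp <- run_bp(1)
  gap <- v98(plan_bp$dose, masks$PTV, rx) - v98_target
  steps <- 0L
  while (abs(gap) > v98_tol && steps < max_bisect) {
    steps <- steps + 1L
    mid <- sqrt(lo * hi)
    plan_try <- run_bp(mid)
    gap_try <- v98(plan_try$dose, masks$PTV, rx) - v98_target
    if (abs(gap_try) <= abs(gap)) {
      plan_bp <- plan_try; gap <- gap_try
    }
    if (gap_try < 0) lo <- mid else hi <- mid
    if (abs(gap) <= v98_tol) break
  }
  if (abs(gap) > v98_tol) {
    rlang::abort(sprintf(
      "coverage matching failed: |V98 difference| = %.4f > %.4f after %d bisection steps.",
      abs(gap), v98_tol, max_bisect))
  }
  pack <- function(plan) {
    m <- plan_metrics(plan$dose, ranked, masks$CPG, masks$PTV, rx)
    s <- saliva_predict(m$subsegment_means$mean_dose, hill)
    list(plan = plan, metrics = m, saliva = s)
  }
  ctl <- pack(control)
  bpp <- pack(plan_bp)
  imp <- improvement_stats(bpp$saliva$s, ctl$saliva$s)
  structure(list(
    control = ctl, bp = bpp, constraints = cons, spec = spec,
    base_plan = bp, ranked = ranked,
    summary = tibble::tibble(
      variant = spec$name,
      v98_control = ctl$metrics$v98, v98_bp = bpp$metrics$v98,
      s1_mean_control = ctl$metrics$subsegment_means$mean_dose[1],
      s1_mean_bp = bpp$metrics$subsegment_means$mean_dose[1],
      whole_mean_control = ctl$metrics$whole_mean,
      whole_mean_bp = bpp$metrics$whole_mean,
      s_control = ctl$saliva$s, s_bp = bpp$saliva$s,
      relative_pct = imp$relative_pct, absolute_pct = imp$absolute_pct
    )
  ), class = "bp_comparison")
}

#' @export
print.bp_comparison <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<bp_comparison> %s vs control at matched V98 (%.3f vs %.3f)\n",
              s$variant, s$v98_bp, s$v98_control))
  cat(sprintf("  S1 mean: %.2f -> %.2f Gy;  S: %.3f -> %.3f (+%d%%)\n",
              s$s1_mean_control, s$s1_mean_bp, s$s_control, s$s_bp,
              as.integer(s$relative_pct)))
  invisible(x)
}

#' @export
tidy.bp_comparison <- function(x, ...) {
  ctl <- x$control$metrics$subsegment_means |>
    dplyr::mutate(plan = "control")
  bpp <- x$bp$metrics$subsegment_means |>
    dplyr::mutate(plan = x$spec$name)
  dplyr::bind_rows(ctl, bpp)
}

#' @export
glance.bp_comparison <- function(x, ...) x$summary
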