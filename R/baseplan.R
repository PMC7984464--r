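#' Specification of one artificial base-plan variant
#'
#' An artificial base plan assigns a uniform dose to each parotid
#' subsegment. Two modes exist: `proportional` scales a reference dose `d0`
#' by each rank's importance factor (rank k gets `d0 * I_k`), while
#' `uniform_subset` assigns a single dose to a chosen set of ranks and zero
#' elsewhere. In both modes ranks outside `included_ranks` get zero.
#'
#' @param name Variant name (e.g. `"BP_30"`).
#' @param mode `"proportional"` or `"uniform_subset"`.
#' @param d0 Reference dose in Gy (proportional mode).
#' @param included_ranks Integer subset of 1..18 receiving dose.
#' @param subset_dose Uniform dose in Gy (uniform_subset mode).
#' @return A `base_plan_spec`.
#' @export
base_plan_spec <- function(name, mode = c("proportional", "uniform_subset"),
                           d0 = NULL, included_ranks = 1:18,
                           subset_dose = NULL) {
  mode <- match.arg(mode)
  included_ranks <- sort(unique(as.integer(included_ranks)))
  if (length(included_ranks) == 0 || !all(included_ranks %in% 1:18)) {
    rlang::abort("`included_ranks` must be a non-empty subset of 1..18.")
  }
  if (mode == "proportional") {
    if (is.null(d0) || d0 <= 0) rlang::abort("proportional mode needs `d0` > 0.")
  } else {
    if (is.null(subset_dose) || subset_dose <= 0) {
      rlang::abort("uniform_subset mode needs `subset_dose` > 0.")
    }
  }
  structure(list(name = name, mode = mode, d0 = d0,
                 included_ranks = included_ranks, subset_dose = subset_dose),
            class = "base_plan_spec")
}

#' @export
print.base_plan_spec <- function(x, ...) {
  cat(sprintf("<base_plan_spec> %s: %s, %s, ranks {%s}\n", x$name, x$mode,
              if (x$mode == "proportional") sprintf("D0 = %g Gy", x$d0)
              else sprintf("%g Gy uniform", x$subset_dose),
              paste(range(x$included_ranks), collapse = "..")))
  invisible(x)
}

#' The five standard base-plan variants
#'
#' Returns the standard family: three proportional variants over all 18
#' ranks with D0 of 10, 20 and 30 Gy (`BP_10`, `BP_20`, `BP_30`), a
#' proportional variant identical to `BP_20` on ranks S1..S5 with all other
#' ranks zeroed (`BP_20,5`), and a uniform 50 Gy assignment to ranks S1..S5
#' (`BP_top5`).
#'
#' @param d0_linear Three D0 values (Gy) for the proportional variants.
#' @param subset_d0 D0 (Gy) for the rank-restricted proportional variant.
#' @param subset_dose Uniform dose (Gy) for the top-5 variant.
#' @return Named list of five [base_plan_spec()]s.
#' @export
make_variant_suite <- function(d0_linear = c(10, 20, 30), subset_d0 = 20,
                               subset_dose = 50) {
  stopifnot(length(d0_linear) == 3)
  specs <- c(
    lapply(d0_linear, function(d0) {
      base_plan_spec(sprintf("BP_%g", d0), "proportional", d0 = d0)
    }),
    list(
      base_plan_spec(sprintf("BP_%g,5", subset_d0), "proportional",
                     d0 = subset_d0, included_ranks = 1:5),
      base_plan_spec("BP_top5", "uniform_subset", included_ranks = 1:5,
                     subset_dose = subset_dose)
    )
  )
  stats::setNames(specs, vapply(specs, function(s) s$name, character(1)))
}

#' Build an artificial base-plan dose distribution
#'
#' Applies the base-plan construction rules: dose outside the CPG is zero;
#' dose in the CPG-PTV overlap is zero (so target coverage is never
#' penalized); within each remaining subsegment the dose is exactly
#' uniform — `d0 * I_k` for rank k in proportional mode, or the subset dose
#' in uniform_subset mode, with ranks outside the included set at zero.
#'
#' @param ranked A ranked `parotid_labelmap` (see [assign_ranks()]).
#' @param ptv_mask A [binary_mask()] of the union of target volumes, on the
#'   same geometry (use a mask of all-`FALSE` voxels for no target).
#' @param spec A [base_plan_spec()].
#' @param scaling Importance scaling factors I1..I18 from
#'   [scaling_factors()] (proportional mode).
#' @return A [dose_grid()] of the base plan.
#' @export
build_base_plan <- function(ranked, ptv_mask, spec, scaling = NULL) {
  stopifnot(inherits(ranked, "parotid_labelmap"), inherits(spec, "base_plan_spec"))
  if (!isTRUE(ranked$ranked)) {
    rlang::abort("label map must be ranked (run assign_ranks() first).")
  }
  if (!same_geometry(ranked, ptv_mask)) {
    rlang::abort("label map and PTV mask must share one grid geometry.")
  }
  per_rank <- numeric(18)
  if (spec$mode == "proportional") {
    if (is.null(scaling) || length(scaling) != 18) {
      rlang::abort("proportional mode needs 18 scaling factors (see scaling_factors()).")
    }
    per_rank[spec$included_ranks] <- spec$d0 * scaling[spec$included_ranks]
  } else {
    per_rank[spec$included_ranks] <- spec$subset_dose
  }
  vals <- array(0, dim = dim(ranked$labels))
  inside <- ranked$labels > 0L & !ptv_mask$voxels
  vals[inside] <- per_rank[ranked$labels[inside]]
  if (!any(inside)) {
    rlang::warn("all CPG voxels overlap the target volumes: base plan is identically zero.")
  }
  dose_grid(vals, ranked$grid$origin, ranked$grid$spacing)
}

#' Optimizer constraint values for a base plan
#'
#' The spatially varying constraint is carried by two numbers handed to the
#' optimizer alongside the loaded base plan: an upper bound on the CPG
#' maximum dose equal to the base plan's maximum plus a margin of 0 to
#' 15 Gy, and the clinical whole-mean bound shifted up by the base plan's
#' mean dose over the CPG (the base-plan dose is absorbed into the gland's
#' mean during optimization, so the bound must rise by exactly that much).
#'
#' @param bp Base-plan [dose_grid()].
#' @param cpg_mask CPG [binary_mask()] on the same geometry.
#' @param clinical_mean_bound Clinical whole-mean CPG bound in Gy (e.g. 20).
#' @param dmax_margin Margin in Gy, within `[0, 15]`.
#' @return A tibble of class `constraint_set` with columns
#'   `cpg_dmax_bound`, `cpg_mean_bound_shifted`, `dmax_margin`,
#'   `bp_max`, `bp_mean_cpg`.
#' @export
constraint_set <- function(bp, cpg_mask, clinical_mean_bound, dmax_margin) {
  if (dmax_margin < 0 || dmax_margin > 15) {
    rlang::abort("`dmax_margin` must lie in [0, 15] Gy.")
  }
  if (!same_geometry(bp, cpg_mask)) {
    rlang::abort("base plan and CPG mask must share one grid geometry.")
  }
  if (!any(cpg_mask$voxels)) rlang::abort("CPG mask is empty.")
  bp_max <- max(bp$values)
  bp_mean <- mean(bp$values[cpg_mask$voxels])
  out <- tibble::tibble(
    cpg_dmax_bound = bp_max + dmax_margin,
    cpg_mean_bound_shifted = clinical_mean_bound + bp_mean,
    dmax_margin = dmax_margin,
    bp_max = bp_max,
    bp_mean_cpg = bp_mean
  )
  class(out) <- c("constraint_set", class(out))
  out
}
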