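#' Mean dose per subsegment rank
#'
#' Arithmetic mean of voxel doses over each rank's voxels, on the dose
#' grid (resample structures/labels onto the dose grid first; no
#' double interpolation is performed here). A rank emptied by contouring
#' or overlap removal is reported as `NA`, not 0.
#'
#' @param dose A [dose_grid()].
#' @param ranked A ranked `parotid_labelmap` on the same geometry.
#' @return A tibble with columns `rank`, `n_voxels`, `mean_dose`.
#' @export
subsegment_means <- function(dose, ranked) {
  if (!same_geometry(dose, ranked)) {
    rlang::abort("dose and label map must share one grid geometry.")
  }
  lab <- ranked$labels
  pos <- lab > 0L
  sums <- vapply(1:18, function(k) sum(dose$values[lab == k]), numeric(1))
  ns <- tabulate(lab[pos], nbins = 18)
  tibble::tibble(
    rank = 1:18,
    n_voxels = ns,
    mean_dose = ifelse(ns > 0, sums / pmax(ns, 1L), NA_real_)
  )
}

#' Mean dose over a mask
#'
#' Equals the unweighted average of the 18 subsegment means whenever the
#' cell volumes are exactly equal.
#'
#' @param dose A [dose_grid()].
#' @param mask A [binary_mask()] on the same geometry.
#' @return Mean dose in Gy.
#' @export
whole_mean <- function(dose, mask) {
  if (!same_geometry(dose, mask)) {
    rlang::abort("dose and mask must share one grid geometry.")
  }
  if (!any(mask$voxels)) rlang::abort("mask is empty.")
  mean(dose$values[mask$voxels])
}

#' Cumulative dose-volume histogram
#'
#' Computed on raw voxel values (differential histogram then reverse
#' cumulative sum, no interpolation): at each dose edge, the fraction of
#' the mask volume receiving at least that dose. The curve starts at 1 at
#' 0 Gy and reaches 0 above the maximum dose.
#'
#' @param dose A [dose_grid()].
#' @param mask A [binary_mask()] on the same geometry.
#' @param bin_width Bin width in Gy (default 0.1).
#' @return A tibble of class `dvh_curve` with columns `dose_edge` (Gy) and
#'   `volume_fraction`.
#' @export
dvh <- function(dose, mask, bin_width = 0.1) {
  if (bin_width <= 0) rlang::abort("`bin_width` must be positive.")
  if (!same_geometry(dose, mask)) {
    rlang::abort("dose and mask must share one grid geometry.")
  }
  if (!any(mask$voxels)) rlang::abort("mask is empty.")
  v <- dose$values[mask$voxels]
  edges <- seq(0, max(v) + bin_width, by = bin_width)
  frac <- vapply(edges, function(e) mean(v >= e), numeric(1))
  out <- tibble::tibble(dose_edge = edges, volume_fraction = frac)
  class(out) <- c("dvh_curve", class(out))
  out
}

#' Volume fraction at or above a dose threshold
#'
#' Reads the cumulative DVH at an arbitrary threshold by exact counting
#' semantics: the fraction at the largest edge not exceeding the
#' threshold... more precisely, the curve is a step function of the
#' underlying voxel values, so `v_at(dvh, t)` returns the fraction of
#' voxels with dose >= t as represented by the stored edges (the edge grid
#' is dense enough at the default bin width that the step is resolved to
#' `bin_width`).
#'
#' @param dvh_curve A `dvh_curve` from [dvh()].
#' @param threshold Dose threshold in Gy.
#' @return Volume fraction in `[0, 1]`.
#' @export
v_at <- function(dvh_curve, threshold) {
  if (threshold <= 0) return(1)
  i <- findInterval(threshold, dvh_curve$dose_edge)
  if (i >= nrow(dvh_curve)) return(0)
  # step function: fraction >= threshold equals fraction at the next edge
  # unless the threshold hits an edge exactly
  if (abs(dvh_curve$dose_edge[i] - threshold) < 1e-9) {
    dvh_curve$volume_fraction[i]
  } else {
    dvh_curve$volume_fraction[i + 1L]
  }
}

#' V98: fraction of a structure receiving at least 98% of prescription
#'
#' @param dose A [dose_grid()].
#' @param mask A [binary_mask()].
#' @param prescription Prescription dose in Gy.
#' @return Fraction in `[0, 1]`.
#' @export
v98 <- function(dose, mask, prescription) {
  if (!same_geometry(dose, mask)) {
    rlang::abort("dose and mask must share one grid geometry.")
  }
  if (!any(mask$voxels)) rlang::abort("mask is empty.")
  mean(dose$values[mask$voxels] >= 0.98 * prescription)
}

#' CPG-target overlap fraction
#'
#' @param cpg CPG [binary_mask()] (non-empty).
#' @param ptv_union Union of target-volume masks, same geometry.
#' @return `|CPG intersect PTV| / |CPG|`.
#' @export
overlap_fraction <- function(cpg, ptv_union) {
  if (!same_geometry(cpg, ptv_union)) {
    rlang::abort("masks must share one grid geometry.")
  }
  n <- sum(cpg$voxels)
  if (n == 0) rlang::abort("CPG mask is empty.")
  sum(cpg$voxels & ptv_union$voxels) / n
}

#' Minimum distance between two masks
#'
#' Minimum Euclidean distance between voxel centers of the two masks
#' (0 if they overlap). Computed through the exact distance transform of
#' the second mask.
#'
#' @param a,b [binary_mask()]s on the same geometry.
#' @return Distance in cm.
#' @export
min_distance <- function(a, b) {
  if (!same_geometry(a, b)) rlang::abort("masks must share one grid geometry.")
  if (!any(a$voxels) || !any(b$voxels)) rlang::abort("both masks must be non-empty.")
  d <- distance_to_mask(b)
  min(d[a$voxels]) / 10
}

#' Paired t test as a tidy one-row summary
#'
#' Two-sided paired t test on matched samples. If the paired differences
#' have zero variance the result is flagged degenerate: `t` is `Inf` (or
#' `NaN` when the mean difference is also zero) and `p` is `NA`.
#'
#' @param a,b Numeric vectors of equal length `n >= 2`.
#' @return A tibble with columns `mean_diff`, `sd_diff`, `t`, `df`, `p`,
#'   `degenerate`.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b)) rlang::abort("`a` and `b` must have equal length.")
  n <- length(a)
  if (n < 2) rlang::abort("need at least 2 pairs.")
  d <- a - b
  sdd <- stats::sd(d)
  if (sdd == 0) {
    return(tibble::tibble(
      mean_diff = mean(d), sd_diff = 0,
      t = if (mean(d) == 0) NaN else Inf * sign(mean(d)),
      df = n - 1L, p = NA_real_, degenerate = TRUE
    ))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  tibble::tibble(
    mean_diff = mean(d), sd_diff = sdd,
    t = unname(tt$statistic), df = as.integer(unname(tt$parameter)),
    p = tt$p.value, degenerate = FALSE
  )
}

#' All plan-evaluation metrics for one dose distribution
#'
#' Convenience wrapper collecting the quantities used to compare plans:
#' per-rank subsegment means, whole-gland mean and maximum dose, target
#' V98, CPG-target overlap fraction and minimum distance.
#'
#' @param dose A [dose_grid()].
#' @param ranked Ranked `parotid_labelmap` of the CPG.
#' @param cpg_mask,ptv_mask [binary_mask()]s on the dose geometry.
#' @param prescription Prescription dose in Gy.
#' @return A list of class `plan_metrics`: `subsegment_means` (tibble),
#'   `whole_mean`, `dmax`, `v98`, `overlap_fraction`, `min_distance_cm`.
#' @export
plan_metrics <- function(dose, ranked, cpg_mask, ptv_mask, prescription) {
  structure(list(
    subsegment_means = subsegment_means(dose, ranked),
    whole_mean = whole_mean(dose, cpg_mask),
    dmax = max(dose$values[cpg_mask$voxels]),
    v98 = v98(dose, ptv_mask, prescription),
    overlap_fraction = overlap_fraction(cpg_mask, ptv_mask),
    min_distance_cm = if (any(cpg_mask$voxels & ptv_mask$voxels)) 0
                      else min_distance(cpg_mask, ptv_mask),
    prescription = prescription
  ), class = "plan_metrics")
}

#' @export
print.plan_metrics <- function(x, ...) {
  cat(sprintf("<plan_metrics> CPG mean %.2f Gy, Dmax %.2f Gy, PTV V98 %.3f, overlap %.3f\n",
              x$whole_mean, x$dmax, x$v98, x$overlap_fraction))
  invisible(x)
}
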