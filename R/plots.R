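#' Plot a cumulative DVH curve
#'
#' @param object A `dvh_curve` from [dvh()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dvh_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$dose_edge,
                                       y = .data$volume_fraction)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::labs(x = "Dose (Gy)", y = "Volume fraction ≥ dose",
                  title = "Cumulative dose-volume histogram") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' Plot one axial slice of a subsegment label map
#'
#' @param object A `parotid_labelmap`.
#' @param slice Axial slice index (default: the slice with the most labeled
#'   voxels).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.parotid_labelmap <- function(object, slice = NULL, ...) {
  d <- dim(object$labels)
  if (is.null(slice)) {
    per_slice <- vapply(seq_len(d[3]), function(k) sum(object$labels[, , k] > 0),
                        numeric(1))
    slice <- which.max(per_slice)
  }
  ax <- axis_coords(object)
  sl <- object$labels[, , slice]
  df <- tibble::tibble(
    x = rep(ax$x, times = d[2]),
    y = rep(ax$y, each = d[1]),
    label = as.vector(sl)
  )
  df <- dplyr::filter(df, .data$label > 0)
  df$label <- factor(df$label, levels = 1:18,
                     labels = paste0("S", 1:18))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$label)) +
    ggplot2::geom_tile(width = object$grid$spacing[1],
                       height = object$grid$spacing[2]) +
    ggplot2::coord_equal() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "x (mm, patient left →)", y = "y (mm, anterior ↑)",
                  fill = if (object$ranked) "Rank" else "Cell",
                  title = sprintf("Subsegments, axial slice z = %.1f mm",
                                  ax$z[slice])) +
    ggplot2::theme_minimal()
}

#' Plot a fitted Hill dose-response curve with its data
#'
#' @param object A `hill_fit` from [fit_hill()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hill_fit <- function(object, ...) {
  dmax <- max(object$data$dose)
  grid <- tibble::tibble(dose = seq(0, dmax, length.out = 200))
  grid$response <- hill_response(grid$dose, object$delta, object$d50,
                                 object$n, object$r0)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$dose,
                                            y = .data$response)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, color = "steelblue") +
    ggplot2::labs(x = "Subsegment dose (Gy)",
                  y = "Saliva output (fraction of baseline)",
                  title = sprintf("Hill fit: Δ = %.3f, D50 = %.1f Gy, n = %.2f",
                                  object$delta, object$d50, object$n)) +
    ggplot2::theme_minimal()
}

#' Plot per-rank mean doses for a control vs base-plan comparison
#'
#' @param object A `bp_comparison` from [matched_coverage_pair()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bp_comparison <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$rank),
                                   y = .data$mean_dose,
                                   fill = .data$plan)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "Subsegment rank", y = "Mean dose (Gy)",
                  fill = NULL,
                  title = "Mean subsegment dose at matched target coverage") +
    ggplot2::theme_minimal()
}
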