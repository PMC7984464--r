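#' Hill-ensemble parameters for the 18 subsegments
#'
#' Each subsegment rank i carries a Hill dose-response triplet: `delta`
#' (maximum loss in salivary output attributable to that subsegment, as a
#' fraction of baseline), `d50` (dose in Gy at which half of `delta` is
#' lost) and `n` (curve steepness). The deltas must sum to at most 1 so
#' the predicted output cannot go below zero at infinite dose.
#'
#' @param table Data frame with columns `rank`, `delta`, `d50`, `n`.
#' @return A tibble of class `hill_params`.
#' @export
hill_params <- function(table) {
  tbl <- tibble::as_tibble(table)
  need <- c("rank", "delta", "d50", "n")
  if (!all(need %in% names(tbl))) {
    rlang::abort(paste0("hill parameters need columns: ",
                        paste(need, collapse = ", ")))
  }
  tbl <- dplyr::arrange(tbl, .data$rank)
  if (!identical(as.integer(tbl$rank), 1:18)) {
    rlang::abort("hill parameters must cover ranks 1..18 exactly once.")
  }
  if (any(tbl$delta < 0) || sum(tbl$delta) > 1 + 1e-12) {
    rlang::abort("deltas must be non-negative and sum to at most 1.")
  }
  if (any(tbl$d50 <= 0) || any(tbl$n <= 0)) {
    rlang::abort("all d50 and n values must be positive.")
  }
  class(tbl) <- c("hill_params", class(tbl))
  tbl
}

#' Synthetic default Hill parameters
#'
#' A self-contained, clearly-synthetic parameter set (the model originally
#' used in the clinic was fit to outputs of an external statistical model
#' that is not redistributable). Deltas decay geometrically with rank in
#' proportion to the synthetic importance profile and sum to 0.65, so even
#' infinite dose everywhere leaves 35% of baseline output; d50 rises
#' gently with rank (less important regions are modelled as less
#' sensitive) and the steepness is 2 throughout.
#'
#' @return A [hill_params()] tibble.
#' @export
hill_params_synthetic <- function() {
  w <- 0.7^(0:17)
  hill_params(tibble::tibble(
    rank = 1:18,
    delta = 0.65 * w / sum(w),
    d50 = 18 + 0.75 * (0:17),
    n = rep(2, 18)
  ))
}

#' Read/write Hill parameters as JSON
#'
#' JSON shape: array of 18 objects `{rank, delta, d50_gy, n}`.
#'
#' @param path File path.
#' @return [hill_params()] for the reader; the path, invisibly, for the
#'   writer.
#' @export
read_hill_params <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  names(raw)[names(raw) == "d50_gy"] <- "d50"
  hill_params(raw)
}

#' @rdname read_hill_params
#' @param params A [hill_params()] tibble.
#' @export
write_hill_params <- function(params, path) {
  out <- lapply(seq_len(nrow(params)), function(i) {
    list(rank = params$rank[i], delta = params$delta[i],
         d50_gy = params$d50[i], n = params$n[i])
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# one Hill loss term: fraction of delta lost at dose D
hill_loss_term <- function(dose, d50, n) {
  1 - 1 / (1 + (dose / d50)^n)
}

#' Single-subsegment Hill response curve
#'
#' `r(D) = r0 - delta * (1 - 1 / (1 + (D / d50)^n))`: the response starts
#' at `r0` at zero dose and declines sigmoidally toward `r0 - delta`,
#' passing `r0 - delta/2` exactly at `D = d50`.
#'
#' @param dose Dose(s) in Gy.
#' @param delta,d50,n Hill parameters.
#' @param r0 Response at zero dose (default 1).
#' @return Response value(s).
#' @export
hill_response <- function(dose, delta, d50, n, r0 = 1) {
  r0 - delta * hill_loss_term(dose, d50, n)
}

#' Predict stimulated saliva output at one year
#'
#' The ensemble model: predicted output (fraction of baseline) is
#' `S = 1 - sum_i delta_i * (1 - 1 / (1 + (D_i / d50_i)^n_i))` over the 18
#' subsegment mean doses. S is 1 at zero dose everywhere, non-increasing
#' in every dose, and bounded below by `1 - sum(delta)`.
#'
#' @param doses 18 subsegment mean doses in Gy (rank order); must be
#'   non-negative and defined (no `NA`).
#' @param params A [hill_params()] tibble.
#' @return A list of class `saliva_prediction`: `s` (fraction of baseline)
#'   and `per_subsegment_loss` (tibble with `rank`, `dose`, `loss`).
#' @export
saliva_predict <- function(doses, params) {
  stopifnot(inherits(params, "hill_params"))
  doses <- as.numeric(doses)
  if (length(doses) != 18) rlang::abort("`doses` must have length 18.")
  if (any(is.na(doses))) {
    rlang::abort("undefined subsegment doses (NA) cannot be predicted; all 18 ranks need a mean dose.")
  }
  if (any(doses < 0)) rlang::abort("doses must be non-negative.")
  loss <- params$delta * hill_loss_term(doses, params$d50, params$n)
  structure(list(
    s = 1 - sum(loss),
    per_subsegment_loss = tibble::tibble(rank = 1:18, dose = doses, loss = loss)
  ), class = "saliva_prediction")
}

#' @export
print.saliva_prediction <- function(x, ...) {
  cat(sprintf("<saliva_prediction> S = %.4f of baseline (total loss %.4f)\n",
              x$s, sum(x$per_subsegment_loss$loss)))
  invisible(x)
}

#' Fit one subsegment's Hill dose-response curve
#'
#' Least-squares fit of `r(D) = r0 - delta * (1 - 1/(1 + (D/d50)^n))` to
#' sampled response points, with `r0` fixed to the observed response at
#' zero dose (curves are generated by varying one subsegment while the
#' others are held constant, so the zero-dose response need not be 1).
#' Bounded Levenberg-Marquardt with 8 deterministic starts over a
#' log-spaced d50 grid; bounds `delta` in [0, 1], `d50` in (0, 200],
#' `n` in (0, 20]. A fitted `delta` at or below `1e-3` flags `d50` and `n`
#' as unidentifiable (there is no dose response to locate); a perfectly
#' flat curve skips fitting entirely and returns `delta = 0` with `d50`
#' and `n` as `NA`.
#'
#' @param dose_points Doses in Gy (>= 5 points, must include 0); the
#'   conventional sampling grid is 0 to 40 Gy in 2 Gy steps.
#' @param responses Responses in `[0, 1]`, same length.
#' @param n_starts Number of multi-start d50 values (default 8).
#' @return An object of class `hill_fit` with elements `delta`, `d50`,
#'   `n`, `r0`, `sse`, `unidentifiable`, `data`.
#' @export
fit_hill <- function(dose_points, responses, n_starts = 8) {
  dose_points <- as.numeric(dose_points)
  responses <- as.numeric(responses)
  if (length(dose_points) != length(responses)) {
    rlang::abort("`dose_points` and `responses` must have equal length.")
  }
  if (length(dose_points) < 5) rlang::abort("need at least 5 dose points.")
  if (min(dose_points) != 0) rlang::abort("`dose_points` must include dose 0.")
  if (any(responses < -1e-9) || any(responses > 1 + 1e-9)) {
    rlang::abort("responses must lie in [0, 1].")
  }
  r0 <- mean(responses[dose_points == 0])
  # a flat curve carries no dose response: nothing to fit, and the
  # least-squares problem is singular, so short-circuit to the flagged result
  if (max(responses) - min(responses) < 1e-9) {
    return(structure(list(
      delta = 0, d50 = NA_real_, n = NA_real_, r0 = r0,
      sse = sum((responses - r0)^2), unidentifiable = TRUE,
      data = tibble::tibble(dose = dose_points, response = responses)
    ), class = "hill_fit"))
  }
  df <- data.frame(d = dose_points, r = responses)
  lower <- c(delta = 0, d50 = 1e-6, n = 1e-6)
  upper <- c(delta = 1, d50 = 200, n = 20)
  d50_starts <- exp(seq(log(2), log(100), length.out = n_starts))
  delta_start <- min(max(r0 - min(responses), 1e-3), 1)
  best <- NULL
  for (s in d50_starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        r ~ r0 - delta * (1 - 1 / (1 + (d / d50)^n)),
        data = df,
        start = list(delta = delta_start, d50 = s, n = 2),
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::residuals(fit)^2)
    if (is.null(best) || sse < best$sse - 1e-15) {
      co <- stats::coef(fit)
      best <- list(delta = unname(co["delta"]), d50 = unname(co["d50"]),
                   n = unname(co["n"]), sse = sse)
    }
  }
  if (is.null(best)) {
    rlang::abort(paste0(
      "Hill fit failed to converge from any of ", n_starts,
      " starts (d50 grid 2..100 Gy); check that the responses vary with dose."))
  }
  structure(list(
    delta = best$delta, d50 = best$d50, n = best$n, r0 = r0,
    sse = best$sse, unidentifiable = best$delta <= 1e-3,
    data = tibble::tibble(dose = dose_points, response = responses)
  ), class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("<hill_fit> delta %.4f, d50 %.2f Gy, n %.2f (r0 %.3f, SSE %.3g)%s\n",
              x$delta, x$d50, x$n, x$r0, x$sse,
              if (x$unidentifiable) " [no dose response: d50/n unidentifiable]" else ""))
  invisible(x)
}

#' @export
tidy.hill_fit <- function(x, ...) {
  tibble::tibble(
    term = c("delta", "d50", "n"),
    estimate = c(x$delta, x$d50, x$n),
    unidentifiable = c(FALSE, x$unidentifiable, x$unidentifiable)
  )
}

#' @export
glance.hill_fit <- function(x, ...) {
  tibble::tibble(sse = x$sse, r0 = x$r0, n_points = nrow(x$data),
                 unidentifiable = x$unidentifiable)
}

#' Fit Hill curves for all 18 subsegments
#'
#' @param curves Tibble with columns `rank`, `dose`, `response` (each rank
#'   sampled on its own dose grid, conventionally 0:2:40 Gy).
#' @return A [hill_params()] tibble (deltas are not renormalized; the
#'   sum-to-one invariant is checked and violated sums raise an error).
#' @export
fit_hill_ensemble <- function(curves) {
  fits <- curves |>
    dplyr::group_by(.data$rank) |>
    dplyr::group_map(function(g, key) {
      f <- fit_hill(g$dose, g$response)
      tibble::tibble(rank = key$rank, delta = f$delta, d50 = f$d50, n = f$n)
    })
  hill_params(dplyr::bind_rows(fits))
}

# round half away from zero, matching clinical reporting conventions
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Improvement of one plan's predicted saliva output over control
#'
#' Relative improvement `100 * (s_plan - s_control) / s_control` and
#' absolute increase `100 * (s_plan - s_control)` in percentage points,
#' both reported rounded to the nearest integer (half away from zero),
#' the printed precision used in clinical summaries. Unrounded values are
#' returned alongside.
#'
#' @param s_plan,s_control Predicted saliva output fractions; `s_control`
#'   must be positive.
#' @return A tibble with columns `relative_pct`, `absolute_pct`,
#'   `relative_raw`, `absolute_raw`.
#' @export
improvement_stats <- function(s_plan, s_control) {
  if (s_control <= 0) rlang::abort("`s_control` must be positive.")
  rel <- 100 * (s_plan - s_control) / s_control
  abs_ <- 100 * (s_plan - s_control)
  tibble::tibble(
    relative_pct = round_half_up(rel),
    absolute_pct = round_half_up(abs_),
    relative_raw = rel,
    absolute_raw = abs_
  )
}

#' Cohort-level saliva response summary per plan type
#'
#' For every phantom/plan combination, predicts saliva output from the 18
#' subsegment mean doses, then summarizes each plan type against the
#' designated control: mean S, improvement statistics on the mean, and a
#' paired t test across phantoms.
#'
#' @param doses Long tibble with columns `phantom`, `plan`, `rank`,
#'   `mean_dose` (18 ranks per phantom/plan).
#' @param params A [hill_params()] tibble.
#' @param control Name of the control plan type (default `"P_0"`).
#' @return A tibble with one row per plan type: `plan`, `mean_s`,
#'   `relative_pct`, `absolute_pct`, `t`, `df`, `p`, `degenerate`.
#' @export
cohort_response <- function(doses, params, control = "P_0") {
  if (!control %in% doses$plan) {
    rlang::abort(paste0("control plan type '", control, "' not found."))
  }
  s_tbl <- doses |>
    dplyr::group_by(.data$phantom, .data$plan) |>
    dplyr::summarise(
      s = saliva_predict(.data$mean_dose[order(.data$rank)], params)$s,
      .groups = "drop"
    )
  wide <- tidyr::pivot_wider(s_tbl, names_from = "plan", values_from = "s")
  s_ctrl <- wide[[control]]
  plans <- setdiff(unique(s_tbl$plan), control)
  rows <- lapply(plans, function(p) {
    sp <- wide[[p]]
    imp <- improvement_stats(mean(sp), mean(s_ctrl))
    tt <- paired_t(sp, s_ctrl)
    tibble::tibble(plan = p, mean_s = mean(sp),
                   relative_pct = imp$relative_pct,
                   absolute_pct = imp$absolute_pct,
                   t = tt$t, df = tt$df, p = tt$p, degenerate = tt$degenerate)
  })
  dplyr::bind_rows(
    tibble::tibble(plan = control, mean_s = mean(s_ctrl),
                   relative_pct = NA_real_, absolute_pct = NA_real_,
                   t = NA_real_, df = NA_integer_, p = NA_real_,
                   degenerate = NA),
    dplyr::bind_rows(rows)
  )
}
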