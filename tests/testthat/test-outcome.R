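test_that("the ensemble predicts full output at zero dose and saturates at 1 - sum(delta)", {
  params <- hill_params_synthetic()
  expect_equal(saliva_predict(rep(0, 18), params)$s, 1)
  floor_s <- 1 - sum(params$delta)
  huge <- saliva_predict(rep(1e6, 18), params)$s
  expect_equal(huge, floor_s, tolerance = 1e-6)
  expect_gt(saliva_predict(rep(60, 18), params)$s, floor_s)
})

test_that("each subsegment loses exactly half its delta at its d50", {
  params <- hill_params_synthetic()
  for (r in c(1, 9, 18)) {
    doses <- rep(0, 18)
    doses[r] <- params$d50[r]
    pred <- saliva_predict(doses, params)
    expect_equal(pred$s, 1 - params$delta[r] / 2, tolerance = 1e-9)
    expect_equal(pred$per_subsegment_loss$loss[r], params$delta[r] / 2,
                 tolerance = 1e-9)
  }
})

test_that("predicted output is non-increasing in every subsegment dose", {
  params <- hill_params_synthetic()
  base <- rep(15, 18)
  s0 <- saliva_predict(base, params)$s
  for (r in 1:18) {
    up <- base
    up[r] <- base[r] + 5
    expect_lt(saliva_predict(up, params)$s, s0)
  }
})

test_that("undefined or negative doses are rejected", {
  params <- hill_params_synthetic()
  expect_error(saliva_predict(c(NA, rep(1, 17)), params), "NA")
  expect_error(saliva_predict(c(-1, rep(1, 17)), params), "non-negative")
  expect_error(saliva_predict(rep(1, 17), params), "length 18")
})

test_that("invalid Hill parameter tables are rejected", {
  tab <- tibble::as_tibble(hill_params_synthetic())
  bad <- tab; bad$delta <- rep(0.1, 18)  # sums to 1.8
  expect_error(hill_params(bad), "sum to at most 1")
  bad <- tab; bad$d50[3] <- 0
  expect_error(hill_params(bad), "positive")
  bad <- tab; bad$rank[1] <- 2L
  expect_error(hill_params(bad), "exactly once")
})

test_that("Hill parameters survive a JSON round trip", {
  params <- hill_params_synthetic()
  f <- withr::local_tempfile(fileext = ".json")
  write_hill_params(params, f)
  back <- read_hill_params(f)
  expect_equal(back$delta, params$delta, tolerance = 1e-12)
  expect_equal(back$d50, params$d50, tolerance = 1e-12)
  expect_equal(back$n, params$n, tolerance = 1e-12)
})

test_that("fitting noiseless Hill samples recovers the generating parameters", {
  doses <- seq(0, 40, by = 2)
  truth <- list(delta = 0.32, d50 = 21, n = 2.4)
  resp <- hill_response(doses, truth$delta, truth$d50, truth$n)
  fit <- fit_hill(doses, resp)
  expect_false(fit$unidentifiable)
  expect_lt(abs(fit$delta - truth$delta) / truth$delta, 0.01)
  expect_lt(abs(fit$d50 - truth$d50) / truth$d50, 0.01)
  expect_lt(abs(fit$n - truth$n) / truth$n, 0.01)
  expect_lt(fit$sse, 1e-10)

  td <- tidy(fit)
  expect_identical(td$term, c("delta", "d50", "n"))
  expect_false(any(td$unidentifiable))
  gl <- glance(fit)
  expect_identical(gl$n_points, length(doses))
})

test_that("a flat response is flagged unidentifiable rather than over-fit", {
  doses <- seq(0, 40, by = 2)
  fit <- fit_hill(doses, rep(0.8, length(doses)))
  expect_true(fit$unidentifiable)
  expect_identical(fit$delta, 0)
  expect_true(is.na(fit$d50))
  expect_equal(fit$r0, 0.8)
})

test_that("fitting tolerates noise: recovered deltas stay near truth on average", {
  doses <- seq(0, 40, by = 2)
  truth <- list(delta = 0.32, d50 = 21, n = 2.4)
  clean <- hill_response(doses, truth$delta, truth$d50, truth$n)
  deltas <- withr::with_seed(97, {
    vapply(seq_len(100), function(i) {
      noisy <- pmin(1, pmax(0, clean + stats::rnorm(length(doses), 0, 0.01)))
      fit_hill(doses, noisy)$delta
    }, numeric(1))
  })
  expect_lt(abs(stats::median(deltas) - truth$delta) / truth$delta, 0.05)
})

test_that("the full-ensemble fit recovers every subsegment from its own curve", {
  params <- hill_params_synthetic()
  doses <- seq(0, 40, by = 2)
  curves <- purrr::map_dfr(1:18, function(r) {
    tibble::tibble(rank = r, dose = doses,
                   response = hill_response(doses, params$delta[r],
                                            params$d50[r], params$n[r]))
  })
  fitted <- fit_hill_ensemble(curves)
  expect_s3_class(fitted, "hill_params")
  expect_equal(fitted$delta, params$delta, tolerance = 0.02)
  expect_equal(fitted$d50, params$d50, tolerance = 0.5)
})

test_that("improvement statistics use round-half-away-from-zero reporting", {
  # 0.54 over 0.48: relative 12.5 -> 13, absolute 6.0 -> 6
  imp <- improvement_stats(0.54, 0.48)
  expect_equal(imp$relative_pct, 13)
  expect_equal(imp$absolute_pct, 6)
  expect_equal(imp$relative_raw, 12.5)
  # 0.59 over 0.48: relative 22.9 -> 23, absolute 11
  imp <- improvement_stats(0.59, 0.48)
  expect_equal(imp$relative_pct, 23)
  expect_equal(imp$absolute_pct, 11)
  # a decline reports negative percentages
  imp <- improvement_stats(0.42, 0.48)
  expect_equal(imp$absolute_pct, -6)
  expect_error(improvement_stats(0.5, 0), "positive")
})

test_that("cohort summaries pair plans against the control phantom by phantom", {
  params <- hill_params_synthetic()
  # three phantoms; the steered plan always shifts dose off rank 1
  doses <- purrr::map_dfr(1:3, function(ph) {
    ctrl <- 20 + ph  # uniform control dose, varies by phantom
    steer <- rep(ctrl, 18); steer[1] <- ctrl - 10; steer[18] <- ctrl + 10
    dplyr::bind_rows(
      tibble::tibble(phantom = ph, plan = "P_0", rank = 1:18, mean_dose = ctrl),
      tibble::tibble(phantom = ph, plan = "P_BP", rank = 1:18, mean_dose = steer)
    )
  })
  out <- cohort_response(doses, params, control = "P_0")
  expect_identical(out$plan, c("P_0", "P_BP"))
  expect_true(is.na(out$t[1]))
  expect_gt(out$mean_s[2], out$mean_s[1])  # steering off rank 1 helps
  expect_gt(out$t[2], 0)
  expect_false(out$degenerate[2])
  expect_identical(out$df[2], 2L)

  # identical plans give a degenerate (zero-variance) comparison
  out2 <- cohort_response(dplyr::bind_rows(
    dplyr::filter(doses, plan == "P_0"),
    dplyr::mutate(dplyr::filter(doses, plan == "P_0"), plan = "P_same")
  ), params, control = "P_0")
  expect_true(out2$degenerate[out2$plan == "P_same"])
  expect_error(cohort_response(doses, params, control = "missing"), "not found")
})
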