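test_that("noise-free exponential models are recovered exactly", {
  ser1 <- polyexp_series(100, 2)
  f1 <- fit_exp_model(ser1, 1, n_starts = 20, seed = 1)
  expect_lt(abs(f1$par[["A1"]] - 100), 1e-6)
  expect_lt(abs(f1$par[["k1"]] - 2), 1e-6)

  ser3 <- polyexp_series(c(70, 20, 10), c(20, 1, 0.05))
  f3 <- fit_exp_model(ser3, 3, n_starts = 100, seed = 2)
  truth <- c(70, 20, 10, 20, 1, 0.05)
  expect_lt(max(abs(unname(f3$par) - truth) / truth), 1e-4)

  # constant series: amplitude collapses, constant absorbs the level
  serc <- tibble::tibble(time_min = sampling_grid, pct_12c = rep(50, 14))
  fc <- fit_exp_model(serc, 1, has_constant = TRUE, n_starts = 20, seed = 1)
  expect_lt(fc$par[["A1"]], 1e-6)
  expect_equal(fc$par[["C"]], 50, tolerance = 1e-6)
  expect_lt(fc$ssr, 1e-10)

  expect_error(fit_exp_model(ser1, 5), "K must be")
  expect_error(fit_exp_model(ser1[1:3, ], 2), "observations")
})

test_that("parameters come back in canonical descending-rate order", {
  ser <- polyexp_series(c(30, 60), c(0.5, 12), noise_sd = 0.2, seed = 5)
  f <- fit_exp_model(ser, 2, n_starts = 40, seed = 3)
  expect_gt(f$par[["k1"]], f$par[["k2"]])
  expect_gt(f$par[["A1"]], 0)
})

test_that("curve stripping recovers well-separated phases", {
  # pure monoexponential: the stripped slope is the exact rate
  ser1 <- polyexp_series(80, 3)
  cs1 <- curve_strip(ser1, 1)
  expect_equal(cs1$k, 3, tolerance = 1e-8)
  expect_equal(cs1$A, 80, tolerance = 1e-6)

  # 100-fold separated biexponential: both phases within 10%
  ser2 <- polyexp_series(c(60, 40), c(10, 0.1))
  cs2 <- curve_strip(ser2, 2)
  expect_lt(abs(cs2$k[1] - 10) / 10, 0.1)
  expect_lt(abs(cs2$k[2] - 0.1) / 0.1, 0.1)
  expect_lt(abs(cs2$A[1] - 60) / 60, 0.1)
  expect_lt(abs(cs2$A[2] - 40) / 40, 0.1)

  # stripping two phases from monoexponential data leaves a tiny second
  # component (or no strippable residual at all)
  cs3 <- suppressWarnings(curve_strip(polyexp_series(100, 2), 2))
  expect_true(is.null(cs3) || min(cs3$A) / 100 < 0.05)
})

test_that("the extra-sum-of-squares F test follows its definition", {
  mk <- function(ssr, p, n = 12) {
    structure(list(ssr = ssr, p = p, n = n), class = "exp_fit")
  }
  # identical SSR: no evidence for the larger model
  t0 <- extra_ss_test(mk(100, 2), mk(100, 4))
  expect_equal(t0$F, 0)
  expect_equal(t0$p, 1)

  t1 <- extra_ss_test(mk(120, 2), mk(100, 4))
  expect_equal(t1$F, 0.8)
  expect_equal(t1$df1, 2)
  expect_equal(t1$df2, 8)
  expect_equal(t1$p, stats::pf(0.8, 2, 8, lower.tail = FALSE))

  # negative numerator clamps
  t2 <- extra_ss_test(mk(90, 2), mk(100, 4))
  expect_equal(t2$F, 0)
  expect_equal(t2$p, 1)

  expect_error(extra_ss_test(mk(100, 4), mk(90, 2)), "more parameters")
  expect_error(extra_ss_test(mk(100, 2, n = 4), mk(90, 4, n = 4)), "degrees")
  expect_error(extra_ss_test(mk(100, 2, n = 12), mk(90, 4, n = 10)),
               "same data")
})

test_that("Holm adjustment is the step-down correction", {
  expect_equal(holm_adjust(0.02), 0.02)
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(rep(1, 4)), rep(1, 4))
  p <- c(0.001, 0.2, 0.04)
  expect_true(all(holm_adjust(p) >= p))
})

test_that("information criteria use the Gaussian-likelihood forms", {
  mk <- function(ssr, p, n) list(ssr = ssr, n = n, p = p)
  ic <- information_criteria(mk(7, 6, 14))
  expect_equal(ic$aic, 14 * log(0.5) + 14)
  expect_equal(ic$bic, 14 * log(0.5) + 7 * log(14))

  # equal SSR, one extra parameter
  a <- information_criteria(mk(10, 4, 14))
  b <- information_criteria(mk(10, 5, 14))
  expect_equal(b$aic - a$aic, 2)
  expect_equal(b$bic - a$bic, log(14))

  # halving the SSR at fixed q lowers AIC by n log 2
  c1 <- information_criteria(mk(10, 4, 14))
  c2 <- information_criteria(mk(5, 4, 14))
  expect_equal(c1$aic - c2$aic, 14 * log(2))

  expect_warning(ic0 <- information_criteria(mk(0, 4, 14)), "zero")
  expect_equal(ic0$aic, -Inf)
})

test_that("leave-one-out cross-validation behaves as expected", {
  ser <- polyexp_series(100, 2)
  cv1 <- cross_validate(ser, 1, n_starts = 5, seed = 1)
  expect_lt(cv1$score, 1e-10)

  # on noisy monoexponential data the overfitted model cannot do better
  sern <- polyexp_series(100, 2, noise_sd = 1, seed = 11)
  cvn1 <- cross_validate(sern, 1, n_starts = 8, seed = 1)
  cvn3 <- cross_validate(sern, 3, n_starts = 8, seed = 1)
  expect_gte(cvn3$score, cvn1$score)

  # permuting observation order leaves the LOO score unchanged
  perm <- sern[sample(nrow(sern)), ]
  cvp <- cross_validate(perm, 1, n_starts = 8, seed = 1)
  expect_equal(cvp$score, cvn1$score, tolerance = 1e-8)
})

test_that("model selection identifies the generating model class", {
  # monoexponential truth
  hits <- 0L
  for (r in 1:5) {
    ser <- polyexp_series(100, 2, noise_sd = 0.5, seed = 20 + r)
    rep <- select_model(ser, seed = r, n_starts = 40, cv_starts = 6)
    if (rep$consensus$model == "1exp") hits <- hits + 1L
  }
  expect_gte(hits, 3L)

  # biexponential with a genuine constant: consensus keeps the constant
  hits_c <- 0L
  for (r in 1:5) {
    ser <- polyexp_series(c(55, 25), c(12, 1.2), C = 20,
                          noise_sd = 0.4, seed = 40 + r)
    rep <- select_model(ser, seed = r, n_starts = 40, cv_starts = 6)
    if (rep$consensus$has_constant) hits_c <- hits_c + 1L
  }
  expect_gte(hits_c, 3L)
})

test_that("SSR is non-increasing along the nested roster", {
  ser <- polyexp_series(c(70, 20, 10), c(20, 1, 0.1), noise_sd = 0.3,
                        seed = 7)
  rep <- select_model(ser, seed = 2, n_starts = 50, cv_starts = 5)
  ssr <- rep$table$ssr
  expect_true(all(diff(ssr) <= 1e-6 * pmax(ssr[-length(ssr)], 1)))
})

test_that("bootstrap bands are reproducible and degenerate without noise", {
  ser <- polyexp_series(100, 2)
  f <- fit_exp_model(ser, 1, n_starts = 10, seed = 1)
  bb <- bootstrap_band(f, n_resamples = 50, seed = 4)
  expect_lt(max(bb$param_ci$upper - bb$param_ci$lower), 1e-6)
  expect_lt(max(bb$band$upper - bb$band$lower), 1e-6)

  sern <- polyexp_series(100, 2, noise_sd = 1, seed = 3)
  fn <- fit_exp_model(sern, 1, n_starts = 10, seed = 1)
  b1 <- bootstrap_band(fn, n_resamples = 100, seed = 9)
  b2 <- bootstrap_band(fn, n_resamples = 100, seed = 9)
  expect_identical(b1$param_ci, b2$param_ci)
  expect_true(all(b1$param_ci$lower <= b1$param_ci$estimate + 1e-9))
  expect_true(all(b1$param_ci$upper >= b1$param_ci$estimate - 1e-9))
})
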