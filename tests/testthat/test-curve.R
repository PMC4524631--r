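# Attrition statistics -> normalisation -> cubic dynamic control function.

test_that("min-max normalisation maps the reference table onto the unit
           square, idempotently", {
  tab <- attrition_table_lower_molar()
  ns <- normalize_minmax(attrition_series(tab$age, tab$index))
  expect_equal(ns$X[1], 0)
  expect_equal(ns$X[length(ns$X)], 1)
  expect_equal(ns$Y[1], 0)
  expect_equal(ns$Y[length(ns$Y)], 1)
  # age 23 -> 0.2142857... = 0.21 at two decimals; index 0.88 -> 0.22
  expect_equal(ns$X[2], 15 / 70, tolerance = 1e-12)
  expect_equal(round(ns$X[2], 2), 0.21)
  expect_equal(ns$Y[2], 0.22, tolerance = 1e-12)
  expect_equal(round(ns$X[5], 2), 0.60)  # age 50
  # idempotence on already-normalised data
  ns2 <- normalize_minmax(attrition_series(ns$X, ns$Y))
  expect_equal(ns2$X, ns$X, tolerance = 1e-12)
  expect_equal(ns2$Y, ns$Y, tolerance = 1e-12)
  expect_error(normalize_minmax(attrition_series(1:4, rep(2, 4))),
               "constant")
})

test_that("cubic fit to the printed normalised table reproduces the
           reference coefficients", {
  # the printed two-decimal normalised table is the fit's input
  ns <- structure(list(X = c(0, 0.21, 0.31, 0.46, 0.6, 0.74, 0.82, 1.0),
                       Y = c(0, 0.22, 0.3, 0.36, 0.44, 0.5, 0.52, 1.0)),
                  class = "NormalizedSeries")
  dcf <- fit_dcf(ns)
  expect_equal(coef(dcf), c(2.899, -3.849, 1.94, -0.013), tolerance = 0.05)
})

test_that("polynomial fitting is exact on polynomial data and interpolates
           with degree + 1 points", {
  t <- seq(0, 1, length.out = 9)
  cub <- fit_dcf(structure(list(X = t, Y = t^3), class = "NormalizedSeries"))
  expect_equal(coef(cub), c(1, 0, 0, 0), tolerance = 1e-10)

  four <- structure(list(X = c(0, 0.3, 0.7, 1), Y = c(0, 0.5, 0.4, 1)),
                    class = "NormalizedSeries")
  f4 <- fit_dcf(four)
  expect_lt(max(abs(f4$residuals)), 1e-12)
  expect_error(fit_dcf(structure(list(X = c(0, 0, 0.5, 1),
                                      Y = c(0, 1, 0.5, 1)),
                                 class = "NormalizedSeries")), "duplicate")
})

test_that("least-squares residuals match the normal-equations oracle and
           sum to zero", {
  ns <- normalize_minmax(attrition_table_lower_molar())
  dcf <- fit_dcf(ns)
  X <- outer(ns$X, 0:3, `^`)
  beta <- solve(crossprod(X), crossprod(X, ns$Y))
  expect_equal(coef(dcf), rev(as.numeric(beta)), tolerance = 1e-9)
  pred <- evaluate_dcf(dcf, ns$X, clamp = FALSE)
  expect_lt(abs(sum(ns$Y - pred)), 1e-8)
  expect_equal(sqrt(mean(dcf$residuals^2)),
               sqrt(mean((ns$Y - X %*% beta)^2)), tolerance = 1e-9)
})

test_that("evaluation clamps the slight endpoint under/overshoot", {
  dcf <- structure(list(coefficients = c(2.899, -3.849, 1.94, -0.013),
                        degree = 3L, clamp = TRUE, residuals = 0),
                   class = "DynamicControlFunction")
  expect_equal(evaluate_dcf(dcf, 0, clamp = FALSE), -0.013)
  expect_equal(evaluate_dcf(dcf, 0), 0)
  expect_equal(evaluate_dcf(dcf, 1), 2.899 - 3.849 + 1.94 - 0.013,
               tolerance = 1e-12)
  expect_error(evaluate_dcf(dcf, 1.5), "\\[0, 1\\]")
  zero <- structure(list(coefficients = c(0, 0, 0, 0), degree = 3L,
                         clamp = TRUE, residuals = 0),
                    class = "DynamicControlFunction")
  expect_true(all(evaluate_dcf(zero, seq(0, 1, 0.1)) == 0))
})

test_that("schedules: two frames, identity DCF gives a uniform grid,
           non-monotone fits are monotonized", {
  ident <- structure(list(coefficients = c(0, 0, 1, 0), degree = 3L,
                          clamp = TRUE, residuals = 0),
                     class = "DynamicControlFunction")
  expect_equal(nonlinear_schedule(ident, 6L), seq(0, 1, 0.2),
               tolerance = 1e-12)
  two <- structure(list(coefficients = c(2.899, -3.849, 1.94, -0.013),
                        degree = 3L, clamp = TRUE, residuals = 0),
                   class = "DynamicControlFunction")
  expect_equal(nonlinear_schedule(two, 2L), c(0, 0.977), tolerance = 1e-12)
  wavy <- structure(list(coefficients = c(0, -1, 1, 0.3), degree = 3L,
                         clamp = TRUE, residuals = 0),
                    class = "DynamicControlFunction")
  expect_message(u <- nonlinear_schedule(wavy, 20L), "monotonized")
  expect_true(all(diff(u) >= 0))
})

test_that("the fitted curve is steep in the first and last age phases and
           flat in the middle", {
  dcf <- fit_dcf(normalize_minmax(attrition_table_lower_molar()))
  t <- seq(0, 1, length.out = 100)
  u <- evaluate_dcf(dcf, t, clamp = FALSE)
  slope <- diff(u) / diff(t)
  mid <- t[-1] > 0.25 & t[-1] <= 0.7
  early <- t[-1] <= 0.25
  late <- t[-1] > 0.7
  expect_gt(mean(slope[early]), mean(slope[mid]))
  expect_gt(mean(slope[late]), mean(slope[mid]))
})
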