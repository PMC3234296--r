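test_that("curve construction validates its invariants", {
  expect_s3_class(amplification_curve(1:40, rnorm(40, 10)),
                  "amplification_curve")
  expect_error(amplification_curve(c(1, 2, 2, 3), rnorm(4)),
               class = "qe_invalid_input")
  expect_error(amplification_curve(1:4, c(1, 2, NA, 4)),
               class = "qe_invalid_input")
  expect_error(amplification_curve(1:3, 1:4), class = "qe_invalid_input")
})

test_that("standard baseline correction subtracts the first-five mean", {
  f <- c(rep(10, 5), 10 + 2^(1:35))
  cv <- baseline_correct(amplification_curve(1:40, f), "standard")
  expect_equal(cv$fluorescence[1:5], rep(0, 5))
  expect_equal(cv$baseline_state, "standard")
  # offset invariance: adding a constant changes nothing after correction
  cv_k <- baseline_correct(amplification_curve(1:40, f + 37.5), "standard")
  expect_equal(cv_k$fluorescence, cv$fluorescence)
  # re-correcting is an error
  expect_error(baseline_correct(cv, "standard"), class = "qe_invalid_input")
})

test_that("dynamic-tube correction recovers a known baseline", {
  true_baseline <- 25
  cv <- simulate_curve(1.8, F0 = true_baseline, amplitude = 100)
  corrected <- baseline_correct(cv, "dynamic_tube")
  recovered <- cv$fluorescence - corrected$fluorescence
  expect_lt(abs(recovered[1] - true_baseline), 0.05 * 100)
})

test_that("dynamic-tube falls back to standard on a constant curve", {
  cv <- amplification_curve(1:40, rep(5, 40))
  expect_warning(out <- baseline_correct(cv, "dynamic_tube"),
                 class = "qe_baseline_fallback")
  expect_equal(out$fluorescence, rep(0, 40))
})

test_that("adaptive correction subtracts the lower-quartile median", {
  f <- c(rep(c(9, 11), 10), 50 + 1:20)
  cv <- baseline_correct(amplification_curve(1:40, f), "adaptive")
  expect_equal(cv$fluorescence, f - median(f[f <= quantile(f, 0.25)]))
})

test_that("sigmoid fit recovers exact logistic parameters", {
  cyc <- 1:40
  truth <- list(F0 = 3.2, a = 87.5, chalf = 24.3, b = 1.7)
  f <- truth$F0 + truth$a / (1 + exp(-(cyc - truth$chalf) / truth$b))
  fit <- fit_sigmoid(amplification_curve(cyc, f))
  for (p in names(truth))
    expect_equal(fit[[p]], truth[[p]], tolerance = 1e-6, info = p)
  expect_lt(fit$sse, 1e-10)
})

test_that("flat curves raise the no-amplification condition", {
  cv <- amplification_curve(1:40, rep(8, 40))
  expect_error(fit_sigmoid(cv), class = "qe_no_amplification")
  expect_equal(estimate_efficiency(cv)$E, 1)
  expect_equal(estimate_efficiency(simulate_curve(1))$E, 1)
})

test_that("second-derivative maximum has the logistic closed form", {
  expect_equal(second_derivative_max(list(chalf = 25, b = 1)),
               25 - log(2 + sqrt(3)))
  expect_equal(second_derivative_max(list(chalf = 25, b = 1)), 23.683,
               tolerance = 1e-4)
  # b -> 0 limit collapses onto the midpoint
  expect_equal(second_derivative_max(list(chalf = 25, b = 1e-9)), 25,
               tolerance = 1e-6)
  expect_error(second_derivative_max(list(chalf = 25, b = -1)),
               class = "qe_fit_error")
  # numeric oracle: arg-max of finite-difference second derivative
  params <- list(F0 = 0, a = 100, chalf = 22.4, b = 2.3)
  grid <- seq(1, 40, by = 1e-3)
  fg <- params$F0 + params$a / (1 + exp(-(grid - params$chalf) / params$b))
  d2 <- diff(diff(fg))
  numeric_argmax <- grid[which.max(d2) + 1L]
  expect_equal(second_derivative_max(params), numeric_argmax,
               tolerance = 0.01)
})

test_that("noise-free efficiency recovery at the duplication endpoint", {
  expect_equal(estimate_efficiency(simulate_curve(2))$E, 2, tolerance = 0.01)
  expect_equal(estimate_efficiency(simulate_curve(1.5))$E, 1.5,
               tolerance = 0.01)
})

test_that("the anchor cycle precedes the second-derivative maximum", {
  for (E in c(1.3, 1.5, 1.7, 1.9)) {
    est <- estimate_efficiency(simulate_curve(E))
    expect_lt(est$n, est$cpD2)
  }
})

test_that("efficiency is invariant to trace scaling and additive baseline", {
  cv <- simulate_curve(1.8)
  e0 <- estimate_efficiency(cv)$E
  scaled <- amplification_curve(cv$cycles, cv$fluorescence * 7.3)
  shifted <- amplification_curve(cv$cycles, cv$fluorescence + 55)
  expect_equal(estimate_efficiency(scaled)$E, e0, tolerance = 1e-6)
  expect_equal(estimate_efficiency(shifted)$E, e0, tolerance = 1e-6)
})

test_that("estimator recovery under multiplicative noise", {
  set.seed(7)
  errs <- vapply(1:200, function(i) {
    true_E <- runif(1, 1.05, 2)
    cv <- simulate_curve(true_E, noise = 0.01, seed = 1000 + i)
    est <- tryCatch(estimate_efficiency(cv)$E, qpcrEff_error = function(e) 1)
    abs(est - true_E)
  }, numeric(1))
  expect_lt(median(errs), 0.02)
})

test_that("curve CSV readers handle long and wide layouts", {
  long <- tempfile(fileext = ".csv")
  w1 <- simulate_curve(1.9, seed = 1)
  w2 <- simulate_curve(1.6, seed = 2)
  df <- rbind(data.frame(well = "A1", cycle = w1$cycles,
                         fluorescence = w1$fluorescence),
              data.frame(well = "B1", cycle = w2$cycles,
                         fluorescence = w2$fluorescence))
  readr::write_csv(df, long)
  curves <- read_curves_csv(long)
  expect_named(curves, c("A1", "B1"))
  expect_equal(curves$A1$fluorescence, w1$fluorescence)

  wide <- tempfile(fileext = ".csv")
  readr::write_csv(data.frame(cycle = w1$cycles, A1 = w1$fluorescence,
                              B1 = w2$fluorescence), wide)
  curves_w <- read_curves_csv(wide)
  expect_equal(curves_w$B1$fluorescence, curves$B1$fluorescence)

  est <- estimate_efficiencies(curves)
  expect_equal(nrow(est), 2L)
  expect_equal(est$E, c(1.9, 1.6), tolerance = 0.01)
})
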