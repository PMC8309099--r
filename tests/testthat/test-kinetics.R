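test_that("truncate_to_60 keeps only the points at or below 60% release", {
  p <- make_profile(c(15, 30, 45, 60, 75), c(10, 30, 55, 70, 95))
  tr <- truncate_to_60(p)
  expect_equal(tr$release, c(10, 30, 55))
  expect_equal(tr$times, c(15, 30, 45))
  # identity when nothing exceeds 60; empty when everything does
  low <- make_profile(c(15, 30), c(10, 20))
  expect_equal(truncate_to_60(low)$release, low$release)
  high <- make_profile(c(15, 30), c(65, 80))
  expect_length(truncate_to_60(high)$times, 0)
  expect_equal(p$release, c(10, 30, 55, 70, 95))  # input untouched
})

test_that("zero-order fit recovers exact linear release", {
  p <- make_profile(c(0, 5, 10, 25), 4 * c(0, 5, 10, 25))
  f <- fit_zero_order(p)
  expect_equal(f$rate_constant, 4)
  expect_equal(f$r_squared, 1)
  expect_equal(f$mpe, 0)
  expect_false(f$truncated_at_60)
  expect_error(fit_zero_order(make_profile(c(0, 15), c(0, 5))),
               class = "dissolkin_model_skip")
  # constant release has no usable regression
  expect_error(fit_zero_order(make_profile(c(0, 15, 30), c(50, 50, 50))),
               class = "dissolkin_model_skip")
})

test_that("first-order fit works on the log-remaining scale", {
  t <- c(0, 30, 60, 120, 240)
  q <- 100 * (1 - 10^(-0.01 * t))
  f <- fit_first_order(make_profile(t, q))
  expect_equal(f$slope, -0.01, tolerance = 1e-9)
  expect_equal(f$rate_constant, 0.01 * log(10), tolerance = 1e-9)
  expect_equal(f$r_squared, 1)
  expect_equal(f$mpe, 0, tolerance = 1e-9)
  # points at 100% carry no information about remaining drug
  expect_error(fit_first_order(make_profile(c(15, 30, 45),
                                            c(99.9, 99.99, 100))),
               class = "dissolkin_model_skip")
})

test_that("Higuchi and Korsmeyer-Peppas fits recover exact power-law data", {
  p <- make_profile(c(1, 4, 9), c(20, 40, 60))
  fh <- fit_higuchi(p)
  expect_equal(fh$rate_constant, 20, tolerance = 1e-12)
  expect_equal(fh$r_squared, 1)
  expect_true(fh$truncated_at_60)

  # nesting: square-root data is the n = 0.5 special case of the power law
  fk <- fit_korsmeyer_peppas(p)
  expect_equal(fk$exponent_n, 0.5, tolerance = 1e-12)
  expect_equal(fk$rate_constant, 20, tolerance = 1e-9)

  t <- c(1, 2, 3, 4, 5, 6)
  fk2 <- fit_korsmeyer_peppas(make_profile(t, 10 * t^0.941))
  expect_equal(fk2$exponent_n, 0.941, tolerance = 1e-9)
  expect_equal(fk2$rate_constant, 10, tolerance = 1e-6)
  expect_equal(fk2$r_squared, 1)

  # linear data is the n = 1 special case
  fk3 <- fit_korsmeyer_peppas(make_profile(t, 1.2 * t))
  expect_equal(fk3$exponent_n, 1, tolerance = 1e-12)

  # fast-release profiles leave too few usable points
  fast <- make_profile(c(15, 30, 45), c(55, 90, 99))
  expect_error(fit_higuchi(fast), class = "dissolkin_model_skip")
  expect_error(fit_korsmeyer_peppas(fast), class = "dissolkin_model_skip")
})

test_that("MPE is the mean absolute relative error in percent", {
  expect_equal(as.vector(compute_mpe(50, 55)), 10)
  expect_equal(as.vector(compute_mpe(c(25, 50), c(30, 45))), 15)
  expect_equal(as.vector(compute_mpe(c(10, 20), c(10, 20))), 0)
  withzero <- compute_mpe(c(0, 50), c(1, 55))
  expect_equal(as.vector(withzero), 10)
  expect_equal(attr(withzero, "n_excluded"), 1)
  expect_error(compute_mpe(c(0, 0), c(1, 2)),
               class = "dissolkin_computation_error")
  expect_error(compute_mpe(1:3, 1:2), class = "dissolkin_argument_error")
})

test_that("best-model selection ranks by R2, then MPE, then parsimony", {
  tab <- data.frame(
    model = c("zero_order", "first_order", "higuchi", "korsmeyer_peppas"),
    r_squared = c(0.998, 0.976, 0.971, 0.994),
    mpe = c(4.74, 22.65, 20.63, 5.07)
  )
  expect_equal(select_best_model(tab), "zero_order")
  tab$r_squared <- c(0.838, 0.905, 0.953, 0.923)
  tab$mpe <- c(43.18, 37.43, 17.72, 19.48)
  expect_equal(select_best_model(tab), "higuchi")
  # exact R2 tie resolved by MPE, then by parsimony
  tie <- data.frame(model = c("zero_order", "korsmeyer_peppas"),
                    r_squared = c(1, 1), mpe = c(3, 1))
  expect_equal(select_best_model(tie), "korsmeyer_peppas")
  tie$mpe <- c(0, 0)
  expect_equal(select_best_model(tie), "zero_order")
  expect_error(select_best_model(list()),
               class = "dissolkin_selection_error")
})

test_that("mechanism classification uses the cylindrical thresholds", {
  expect_equal(classify_mechanism(0.30), "fickian")
  expect_equal(classify_mechanism(0.45), "anomalous")
  expect_equal(classify_mechanism(0.88), "anomalous")
  expect_equal(classify_mechanism(0.89), "case_II")
  expect_equal(classify_mechanism(1.0), "case_II")
  expect_equal(classify_mechanism(1.001), "super_case_II")
  expect_equal(classify_mechanism(c(0.941, 1.030)),
               c("case_II", "super_case_II"))
  expect_error(classify_mechanism(Inf), class = "dissolkin_argument_error")
})

test_that("analyze_profile applies the fast-release guard and assembles a report", {
  # a profile at 100% by the second point: only zero- and first-order apply
  fast <- make_profile(c(15, 30, 45, 60), c(55, 85, 99, 100))
  rep <- analyze_profile(fast)
  expect_setequal(names(rep$fits), c("zero_order", "first_order"))
  expect_setequal(rep$skipped_models$model, c("higuchi", "korsmeyer_peppas"))
  expect_true(all(rep$skipped_models$reason == "fast drug release"))
  expect_equal(rep$mechanism, "not_applicable")

  # a 24 h sustained profile supports all four models
  slow <- oracle_profile("higuchi", list(k = 1.5))
  rep2 <- analyze_profile(slow)
  expect_setequal(names(rep2$fits),
                  c("zero_order", "first_order", "higuchi", "korsmeyer_peppas"))
  expect_equal(rep2$best_model, "higuchi")

  # every model wins on its own noise-free data (parsimony breaks the
  # exact ties with the power law)
  cases <- list(zero_order = list(k = 0.04), first_order = list(k = 0.002),
                higuchi = list(k = 1.5),
                korsmeyer_peppas = list(k = 0.2, n = 0.75))
  for (m in names(cases)) {
    r <- analyze_profile(oracle_profile(m, cases[[m]]))
    expect_equal(r$best_model, m)
    expect_equal(r$fits[[m]]$r_squared, 1, tolerance = 1e-9)
    expect_equal(r$fits[[m]]$mpe, 0, tolerance = 1e-9)
  }
  expect_error(analyze_profile(make_profile(c(15, 30), c(70, 100))),
               class = "dissolkin_analysis_error")
})

test_that("rate constants are recovered from noisy simulated data", {
  grid13 <- seq(15, 195, by = 15)
  z <- simulate_profile("zero_order", list(k = 0.07), schedule = seq(0, 1440, 120),
                        noise_sd = 1, seed = 101)[[1]]
  expect_lt(abs(fit_zero_order(z)$rate_constant - 0.07) / 0.07, 0.10)

  fo <- simulate_profile("first_order", list(k = 0.01), schedule = grid13,
                         noise_sd = 0.5, seed = 102)[[1]]
  expect_lt(abs(fit_first_order(fo)$rate_constant - 0.01) / 0.01, 0.10)

  h <- simulate_profile("higuchi", list(k = 6.5), noise_sd = 1, seed = 103)[[1]]
  expect_lt(abs(fit_higuchi(h)$rate_constant - 6.5) / 6.5, 0.10)
})

test_that("transformed-scale R2 is invariant to affine rescaling of the predictor", {
  p_min <- make_profile(c(10, 25, 50, 90, 130), c(8, 17, 33, 55, 70))
  p_hr <- make_profile(c(10, 25, 50, 90, 130) / 60, c(8, 17, 33, 55, 70))
  expect_equal(fit_zero_order(p_min)$r_squared, fit_zero_order(p_hr)$r_squared)
  expect_equal(fit_first_order(p_min)$r_squared, fit_first_order(p_hr)$r_squared)
})
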