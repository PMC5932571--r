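zfet_concs <- c(0.01, 0.05, 0.1, 0.5, 1, 2.5, 5, 50, 100)

test_that("4PL fit recovers exact generating parameters from noise-free data", {
  truth <- list(bottom = 0, top = 1, log_ec50 = 0.5, hill_slope = 2)
  resp <- four_pl(zfet_concs, truth$bottom, truth$top, truth$log_ec50, truth$hill_slope)
  # exact proportions (n large enough that counts are not rounded)
  d <- dose_response_data(zfet_concs, rep(1e6, length(zfet_concs)), resp * 1e6)
  fit <- fit_4pl(d)
  expect_lt(abs(fit$ec50 - 10^0.5) / 10^0.5, 1e-6)
  expect_lt(abs(fit$hill_slope - 2), 1e-6)
  expect_lt(abs(fit$bottom), 1e-6)
  expect_lt(abs(fit$top - 1), 1e-6)
})

test_that("EC50 is scale-equivariant in the dose unit", {
  truth <- list(bottom = 0, top = 1, log_ec50 = 0.5, hill_slope = 1.5)
  resp <- four_pl(zfet_concs, 0, 1, 0.5, 1.5)
  f1 <- fit_4pl(dose_response_data(zfet_concs, rep(1e6, 9), resp * 1e6))
  f2 <- fit_4pl(dose_response_data(zfet_concs * 10, rep(1e6, 9), resp * 1e6))
  expect_equal(f2$ec50 / f1$ec50, 10, tolerance = 1e-6)
})

test_that("binomial sampling round-trips the EC50 within simulation error", {
  truth <- list(bottom = 0, top = 1, log_ec50 = 0.5, hill_slope = 2)
  rel_err <- function(n, seed) {
    d <- gen_zfet_outcomes(truth, zfet_concs, n_per_conc = n, seed = seed)
    fit <- suppressWarnings(fit_4pl(d))
    abs(fit$ec50 - 10^0.5) / 10^0.5
  }
  # the embryo-test design (10 per concentration): typical error within 25%
  errs10 <- vapply(1:20, function(s) rel_err(10, s), numeric(1))
  expect_lt(stats::median(errs10), 0.25)
  # 50 per concentration: within 25% for every seed tried
  errs50 <- vapply(1:10, function(s) rel_err(50, s), numeric(1))
  expect_true(all(errs50 < 0.25))
})

test_that("degenerate and awkward response patterns are flagged, not hidden", {
  all_dead <- dose_response_data(zfet_concs, rep(10, 9), rep(10, 9))
  expect_error(fit_4pl(all_dead), "non-estimable")
  all_alive <- dose_response_data(zfet_concs, rep(10, 9), rep(0, 9))
  expect_error(fit_4pl(all_alive), "non-estimable")
  few <- dose_response_data(c(1, 2, 5), rep(10, 3), c(1, 5, 9))
  expect_error(fit_4pl(few), ">= 4")
  # monotone-violating toy data: converges, but EC50 is poorly determined
  wobble <- dose_response_data(zfet_concs, rep(10, 9),
                               c(2, 3, 1, 4, 3, 6, 4, 8, 7))
  expect_warning(fit <- fit_4pl(wobble), "poorly determined|confidence")
  expect_true(fit$converged)
  expect_gt(fit$ec50_ci[["upper"]] / fit$ec50_ci[["lower"]], 10)
})

test_that("internal dose metric is the molar concentration times BCF", {
  expect_equal(internal_dose_metric(100, 451.6), 45.16, ignore_attr = TRUE)
  expect_equal(internal_dose_metric(100, compute_bcf(112.9, 0.25)), 45.16,
               ignore_attr = TRUE)
  # BCF of 1 makes mmol/L and mmol/kg numerically identical
  expect_equal(internal_dose_metric(250, 1), 0.25, ignore_attr = TRUE)
  # linear in both arguments
  expect_equal(internal_dose_metric(30, 100), 3 * internal_dose_metric(10, 100))
  expect_equal(internal_dose_metric(10, 300), 3 * internal_dose_metric(10, 100))
  expect_true(isTRUE(attr(internal_dose_metric(1, 1), "approximate")))
  expect_error(internal_dose_metric(0, 10), "external_conc_um")
  expect_error(internal_dose_metric(1, -1), "bcf")
})

test_that("internal-dose ratios reproduce the reported cross-compound folds", {
  # reported internal metrics (mmol/kg): lethal 316.7 vs 51.75,
  # sub-lethal 25.1 vs 0.47, no-toxic-effect 14.65 vs 2.25
  expect_equal(round(fold_difference(316.7, 51.75)), 6)
  expect_gte(fold_difference(25.1, 0.47), 50)
  expect_lte(fold_difference(14.65, 2.25), 7)
})

test_that("dose-response table validation catches malformed inputs", {
  expect_error(dose_response_data(c(1, 1, 2, 5), rep(10, 4), rep(1, 4)), "distinct")
  expect_error(dose_response_data(c(1, 2), c(10, 10), c(11, 0)), "between 0 and")
  expect_error(dose_response_data(c(-1, 2), c(10, 10), c(1, 1)), "non-negative")
})
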