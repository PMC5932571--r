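test_that("closed-form one-compartment solution matches hand values", {
  expect_equal(simulate_one_compartment(params_whole, scenario_8_48, 0), 0)
  # uptake: C(8) = (k_in/k_out) c_w (1 - e^{-k_out 8})
  c8 <- 112.9 / 0.25 * 0.98 * (1 - exp(-0.25 * 8))
  expect_equal(simulate_one_compartment(params_whole, scenario_8_48, 8), c8)
  expect_equal(c8, 382.67, tolerance = 1e-4)
  # depuration: 48 h at k_out 0.25 leaves e^{-12} of the 8-h level --
  # a one-compartment washout cannot explain double-digit percent retention
  c56 <- simulate_one_compartment(params_whole, scenario_8_48, 56)
  expect_equal(c56, c8 * exp(-12))
  expect_lt(100 * c56 / c8, 0.01)
})

test_that("numerical integration agrees with the closed form to 1e-6", {
  grid <- c(0.1, 0.25, 1, 3, 6, 8, 9, 11, 14, 20, 26, 32, 44, 56)
  cases <- list(
    list(p = params_whole, s = scenario_8_48),
    list(p = one_compartment_params(12.9, 0.025), s = scenario_8_48),
    list(p = one_compartment_params(500, 90), s = exposure_scenario(0.5, 10, 48)),
    list(p = one_compartment_params(1, 0.01), s = exposure_scenario(2, 24, 24))
  )
  for (cs in cases) {
    tt <- grid[grid <= cs$s$t_uptake + cs$s$t_depuration]
    cf <- simulate_one_compartment(cs$p, cs$s, tt)
    od <- simulate_one_compartment(cs$p, cs$s, tt, method = "ode")
    # relative error where the solution is above numerical extinction
    keep <- cf > 1e-12 * max(cf)
    expect_lt(max(abs(cf[keep] - od[keep]) / cf[keep]), 1e-6)
  }
})

test_that("uptake rises toward steady state; depuration decays toward zero", {
  up <- simulate_one_compartment(params_whole, scenario_8_48, seq(0.1, 8, by = 0.1))
  css <- 112.9 / 0.25 * 0.98
  expect_true(all(diff(up) > 0))
  expect_true(all(up < css))
  dep <- simulate_one_compartment(params_whole, scenario_8_48, seq(8, 56, by = 0.5))
  expect_true(all(diff(dep) < 0))
  expect_true(all(dep > 0))
})

test_that("time validation rejects unsorted or negative grids", {
  expect_error(simulate_one_compartment(params_whole, scenario_8_48, c(3, 1)), "sorted")
  expect_error(simulate_one_compartment(params_whole, scenario_8_48, c(-1, 2)), "non-negative")
})

test_that("noise-free fit recovers the generating rates to 1e-6", {
  tc <- gen_timecourse(params_whole, scenario_8_48, n_replicates = 1,
                       noise = noise_model(cv = 0, seed = 1))
  fit <- fit_one_compartment(tc, scenario_8_48)
  expect_lt(abs(fit$params$k_in - 112.9) / 112.9, 1e-6)
  expect_lt(abs(fit$params$k_out - 0.25) / 0.25, 1e-6)
  expect_true(fit$converged)
  expect_length(fit$residuals, nrow(fit$data))
})

test_that("fit under 6% replicate noise recovers rates within 15%", {
  tc <- gen_timecourse(params_whole, scenario_8_48, n_replicates = 16,
                       noise = noise_model(cv = 0.06, seed = 42))
  fit <- fit_one_compartment(tc, scenario_8_48)
  expect_lt(abs(fit$params$k_in - 112.9) / 112.9, 0.15)
  expect_lt(abs(fit$params$k_out - 0.25) / 0.25, 0.15)
  expect_gt(fit$params$se_k_in, 0)
  expect_gt(fit$params$se_k_out, 0)
})

test_that("log-scale objective also recovers the generating rates", {
  tc <- gen_timecourse(params_whole, scenario_8_48, n_replicates = 16,
                       noise = noise_model(cv = 0.06, seed = 42))
  fit <- fit_one_compartment(tc, scenario_8_48, log_scale = TRUE)
  expect_lt(abs(fit$params$k_in - 112.9) / 112.9, 0.15)
  expect_lt(abs(fit$params$k_out - 0.25) / 0.25, 0.15)
})

test_that("underdetermined or degenerate data raise fitting errors", {
  one_point <- timecourse(data.frame(
    replicate_id = 1, phase = "uptake", time_h = 1, tissue = "whole",
    pigmentation = "WT", conc_mg_per_kg = 50
  ))
  expect_error(fit_one_compartment(one_point, scenario_8_48), ">= 3 distinct time points")
  zeros <- timecourse(data.frame(
    replicate_id = 1, phase = "uptake", time_h = c(1, 2, 3, 4), tissue = "whole",
    pigmentation = "WT", conc_mg_per_kg = 0
  ))
  expect_error(fit_one_compartment(zeros, scenario_8_48), ">= 3 distinct time points")
})
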