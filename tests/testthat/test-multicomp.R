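test_that("per-compartment closed forms match hand values and the ODE oracle", {
  s <- exposure_scenario(0.98, 8, 48)
  sim <- simulate_multi_compartment(params_eye_rest, s, 8)
  expect_equal(sim$eyes, 325 / 0.05 * 0.98 * (1 - exp(-0.05 * 8)))
  expect_equal(sim$eyes, 2100.06, tolerance = 1e-5)
  expect_equal(sim$rest, 143.2 / 0.8 * 0.98 * (1 - exp(-0.8 * 8)))
  expect_equal(sim$rest, 175.13, tolerance = 1e-4)
  tt <- c(0.25, 1, 3, 6, 8, 9, 11, 14, 26, 56)
  cf <- simulate_multi_compartment(params_eye_rest, s, tt)
  od <- simulate_multi_compartment(params_eye_rest, s, tt, method = "ode")
  expect_lt(max(abs(cf$eyes - od$eyes) / cf$eyes), 1e-6)
  keep <- cf$rest > 1e-12 * max(cf$rest)  # rest is numerically extinct by 56 h
  expect_lt(max(abs(cf$rest[keep] - od$rest[keep]) / cf$rest[keep]), 1e-6)
  # no exposure, no uptake
  none <- simulate_multi_compartment(params_eye_rest, exposure_scenario(0, 8, 48), tt)
  expect_true(all(none$eyes == 0) && all(none$rest == 0))
})

test_that("weight-weighted combination mixes correctly and conserves mass", {
  expect_equal(combine_whole_body(500, 500, body_default), 500)
  expect_equal(combine_whole_body(2100.061, 175.1285, body_default),
               0.10 * 2100.061 + 0.90 * 175.1285)
  expect_equal(combine_whole_body(0, 0, body_default), 0)
  # amount(whole) = amount(eyes) + amount(rest) at every time point
  s <- exposure_scenario(0.98, 8, 48)
  tt <- c(0.25, 2, 5, 8, 10, 20, 40, 56)
  sim <- simulate_multi_compartment(params_eye_rest, s, tt)
  whole <- combine_whole_body(sim$eyes, sim$rest, body_default)
  amount_whole <- whole * (body_default$w_eyes + body_default$w_rest)
  amount_parts <- sim$eyes * body_default$w_eyes + sim$rest * body_default$w_rest
  expect_lt(max(abs(amount_whole - amount_parts) / amount_parts), 1e-9)
  expect_error(combine_whole_body(-1, 0, body_default), "non-negative")
})

test_that("identical compartment rates collapse to the one-compartment model", {
  same <- multi_compartment_params(112.9, 0.25, 112.9, 0.25)
  s <- exposure_scenario(0.98, 8, 48)
  tt <- c(1, 4, 8, 12, 30, 56)
  sim <- simulate_multi_compartment(same, s, tt)
  whole <- combine_whole_body(sim$eyes, sim$rest, body_default)
  one <- simulate_one_compartment(params_whole, s, tt)
  expect_equal(whole, one, tolerance = 1e-12)
})

test_that("slow eye compartment dominates late depuration", {
  s <- exposure_scenario(0.98, 8, 48)
  tt <- seq(8, 56, by = 1)
  sim <- simulate_multi_compartment(params_eye_rest, s, tt)
  burden_eyes <- sim$eyes * body_default$w_eyes
  burden_total <- burden_eyes + sim$rest * body_default$w_rest
  frac <- burden_eyes / burden_total
  expect_true(all(diff(frac) >= 0))
  # whole-body log-decay is steeper early (0-6 h) than late (24-48 h)
  whole <- combine_whole_body(sim$eyes, sim$rest, body_default)
  slope_early <- (log(whole[tt == 14]) - log(whole[tt == 8])) / 6
  slope_late <- (log(whole[tt == 56]) - log(whole[tt == 32])) / 24
  expect_lt(slope_early, slope_late)  # both negative; early more negative
})

test_that("joint fit recovers generating rates exactly without noise", {
  s <- exposure_scenario(0.98, 8, 48)
  tc <- gen_timecourse(params_eye_rest, s, n_replicates = 1,
                       noise = noise_model(cv = 0, seed = 1), body = body_default)
  fit <- fit_multi_compartment(tc, tc, body_default, s)
  truth <- c(325, 0.05, 143.2, 0.8)
  est <- with(fit$params, c(k_in_eyes, k_out_eyes, k_in_rest, k_out_rest))
  expect_lt(max(abs(est - truth) / truth), 1e-6)
})

test_that("joint fit under 6% noise recovers all four rates within 20%", {
  s <- exposure_scenario(0.98, 8, 48)
  for (seed in 1:3) {
    tc <- gen_timecourse(params_eye_rest, s, n_replicates = 4,
                         noise = noise_model(cv = 0.06, seed = seed),
                         body = body_default)
    fit <- fit_multi_compartment(tc, tc, body_default, s)
    est <- with(fit$params, c(k_in_eyes, k_out_eyes, k_in_rest, k_out_rest))
    expect_lt(max(abs(est - c(325, 0.05, 143.2, 0.8)) / c(325, 0.05, 143.2, 0.8)), 0.20)
    expect_true(all(fit$params$se > 0))
  }
})

test_that("missing eye data and incompatible series are rejected", {
  s <- exposure_scenario(0.98, 8, 48)
  whole_only <- gen_timecourse(params_whole, s, n_replicates = 2,
                               noise = noise_model(cv = 0, seed = 1))
  expect_error(fit_multi_compartment(whole_only, whole_only, body_default, s),
               "fit_one_compartment")
  # eye series collected beyond the scenario window cannot share the scenario
  long <- gen_timecourse(params_eye_rest, exposure_scenario(0.98, 8, 96),
                         times = c(1, 4, 8, 30, 100), n_replicates = 1,
                         noise = noise_model(cv = 0, seed = 1), body = body_default)
  expect_error(fit_multi_compartment(long, long, body_default, s), "scenario")
})

test_that("elimination half-lives are ln(2)/k_out", {
  hl <- compartment_half_lives(params_eye_rest)
  expect_equal(hl[["eyes"]], log(2) / 0.05)
  expect_equal(hl[["eyes"]], 13.86, tolerance = 1e-3)  # reported as ~13 h
  expect_equal(hl[["rest"]], log(2) / 0.8)
  expect_equal(hl[["rest"]] * 60, 51.98, tolerance = 1e-3)  # reported as ~48 min
  expect_equal(compartment_half_lives(one_compartment_params(1, log(2)))[["whole"]], 1)
})
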