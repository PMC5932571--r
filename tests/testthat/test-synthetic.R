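test_that("zero-noise generation equals the deterministic model exactly", {
  tc <- gen_timecourse(params_whole, scenario_8_48, n_replicates = 2,
                       noise = noise_model(cv = 0, seed = 99))
  truth <- simulate_one_compartment(params_whole, scenario_8_48,
                                    sort(unique(tc$time_h)))
  for (r in 1:2) {
    sub <- tc[tc$replicate_id == r, ]
    expect_equal(sub$conc_mg_per_kg[order(sub$time_h)], truth)
  }
})

test_that("generators are pure functions of parameters and seed", {
  a <- gen_timecourse(params_whole, scenario_8_48, n_replicates = 3,
                      noise = noise_model(cv = 0.06, seed = 7))
  b <- gen_timecourse(params_whole, scenario_8_48, n_replicates = 3,
                      noise = noise_model(cv = 0.06, seed = 7))
  c <- gen_timecourse(params_whole, scenario_8_48, n_replicates = 3,
                      noise = noise_model(cv = 0.06, seed = 8))
  expect_identical(a, b)
  expect_false(identical(a, c))
  p1 <- gen_tissue_panel(c(eyes = 1694), c(WT = 1), 3, noise_model(cv = 0.06, seed = 5))
  p2 <- gen_tissue_panel(c(eyes = 1694), c(WT = 1), 3, noise_model(cv = 0.06, seed = 5))
  expect_identical(p1, p2)
  z1 <- gen_zfet_outcomes(list(bottom = 0, top = 1, log_ec50 = 0, hill_slope = 1),
                          c(0.1, 1, 10), 10, seed = 3)
  z2 <- gen_zfet_outcomes(list(bottom = 0, top = 1, log_ec50 = 0, hill_slope = 1),
                          c(0.1, 1, 10), 10, seed = 3)
  expect_identical(z1, z2)
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- .Random.seed
  invisible(gen_timecourse(params_whole, scenario_8_48, n_replicates = 2,
                           noise = noise_model(cv = 0.06, seed = 7)))
  expect_identical(.Random.seed, before)
})

test_that("multiplicative noise at 6% CV keeps sample means near the curve", {
  n_rep <- 16
  tc <- gen_timecourse(params_whole, scenario_8_48, n_replicates = n_rep,
                       noise = noise_model(cv = 0.06, seed = 2024))
  times <- sort(unique(tc$time_h))
  truth <- simulate_one_compartment(params_whole, scenario_8_48, times)
  for (i in seq_along(times)) {
    obs <- tc$conc_mg_per_kg[tc$time_h == times[i]]
    sem <- 0.06 * truth[i] / sqrt(n_rep)
    expect_lt(abs(mean(obs) - truth[i]), 3 * sem)
  }
})

test_that("multi-compartment generation carries eyes and combined whole body", {
  tc <- gen_timecourse(params_eye_rest, scenario_8_48, n_replicates = 1,
                       noise = noise_model(cv = 0, seed = 1), body = body_default)
  expect_setequal(unique(tc$tissue), c("eyes", "whole"))
  t8 <- tc[tc$time_h == 8, ]
  eyes8 <- t8$conc_mg_per_kg[t8$tissue == "eyes"]
  whole8 <- t8$conc_mg_per_kg[t8$tissue == "whole"]
  sim <- simulate_multi_compartment(params_eye_rest, scenario_8_48, 8)
  expect_equal(eyes8, sim$eyes)
  expect_equal(whole8, combine_whole_body(sim$eyes, sim$rest, body_default))
})

test_that("tissue-panel generator applies line factors and validates inputs", {
  pan <- gen_tissue_panel(c(eyes = 1694, brain = 263), c(WT = 1), n_pools = 5,
                          noise = noise_model(cv = 0, seed = 1))
  expect_setequal(unique(pan$pigmentation), "WT")
  expect_equal(pan$conc_mg_per_kg[pan$tissue == "eyes"], rep(1694, 5))
  expect_error(gen_tissue_panel(c(eyes = 1694), c(WT = -2), 3,
                                noise_model(cv = 0, seed = 1)), "positive folds")
  expect_error(gen_tissue_panel(c(eyes = 1694), c(WT = 1), 0,
                                noise_model(cv = 0, seed = 1)), "n_pools")
})

test_that("embryo-outcome generator respects the response curve limits", {
  flat <- gen_zfet_outcomes(list(bottom = 0, top = 0, log_ec50 = 0, hill_slope = 1),
                            c(0.1, 1, 10, 100), 10, seed = 1)
  expect_true(all(flat$n_responding == 0))
  sat <- gen_zfet_outcomes(list(bottom = 0, top = 1, log_ec50 = 0, hill_slope = 3),
                           c(1000, 10000), 10, seed = 1)
  expect_true(all(sat$n_responding == 10))
  expect_error(gen_zfet_outcomes(list(bottom = -0.5, top = 1, log_ec50 = 0,
                                      hill_slope = 1), c(0.001), 10, seed = 1),
               "outside")
})

test_that("noise model validates its inputs", {
  expect_error(noise_model(cv = -0.1, seed = 1), "cv")
  expect_error(noise_model(cv = 0.06), "seed")
  expect_error(noise_model(kind = "bootstrap", cv = 0.06, seed = 1))
})
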