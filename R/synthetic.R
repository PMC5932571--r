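#' Measurement-noise model
#'
#' Noise applied by the synthetic-data generators. The default is
#' mean-preserving multiplicative lognormal noise with a 6% coefficient of
#' variation, matching the relative scatter of pooled LC-MS/MS homogenate
#' measurements (e.g. 308 +/- 18 mg/kg whole body); additive Gaussian noise
#' is available for robustness testing. The seed is always explicit.
#'
#' @param kind `"multiplicative-lognormal"` or `"additive-normal"`.
#' @param cv Coefficient of variation (multiplicative) or SD as a fraction
#'   of the signal (additive); non-negative, default 0.06.
#' @param seed Integer seed; required.
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(kind = c("multiplicative-lognormal", "additive-normal"),
                        cv = 0.06, seed) {
  kind <- match.arg(kind)
  check_non_negative(cv, "cv")
  if (missing(seed)) stop_invalid("`seed` must be given explicitly (no global RNG state)")
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop_invalid("`seed` must be a single integer")
  }
  structure(list(kind = kind, cv = cv, seed = as.integer(seed)),
            class = "noise_model")
}

# Apply a noise model to a vector of true values (RNG already seeded).
apply_noise <- function(true_values, noise) {
  if (noise$cv == 0) return(true_values)
  n <- length(true_values)
  if (noise$kind == "multiplicative-lognormal") {
    sdlog <- sqrt(log(1 + noise$cv^2))
    true_values * stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  } else {
    pmax(true_values + stats::rnorm(n, sd = noise$cv * true_values), 0)
  }
}

#' Generate a synthetic uptake/depuration time course
#'
#' Simulates the chosen compartment model under an exposure scenario and
#' applies per-replicate measurement noise. With one-compartment parameters
#' the output is a whole-body series; with multi-compartment parameters it
#' contains `eyes` and `whole` series (the whole-body values combined via
#' the body composition). Fully reproducible from the noise model's seed.
#'
#' @param params A [one_compartment_params()] or [multi_compartment_params()].
#' @param scenario An [exposure_scenario()].
#' @param times Sampling times (h since exposure start); defaults to the
#'   standard uptake grid truncated to `t_uptake` plus the depuration grid
#'   offset by `t_uptake`.
#' @param n_replicates Replicates per time point.
#' @param noise A [noise_model()].
#' @param body A [body_composition()]; required for multi-compartment params.
#' @param pigmentation Pigmentation label for the generated records.
#' @return A [timecourse()].
#' @export
gen_timecourse <- function(params, scenario, times = NULL, n_replicates = 4,
                           noise = noise_model(cv = 0.06, seed = 1),
                           body = body_composition(),
                           pigmentation = "WT") {
  stopifnot(inherits(scenario, "exposure_scenario"), inherits(noise, "noise_model"))
  if (is.null(times)) {
    up <- default_uptake_times()
    up <- up[up <= scenario$t_uptake]
    dep <- scenario$t_uptake + default_depuration_times()
    dep <- dep[dep <= scenario$t_uptake + scenario$t_depuration]
    times <- sort(unique(c(up, dep)))
  }
  check_times(times)
  check_positive(n_replicates, "n_replicates")
  phase <- ifelse(times <= scenario$t_uptake, "uptake", "depuration")
  one_series <- function(true_conc, tissue) {
    do.call(rbind, lapply(seq_len(n_replicates), function(r) {
      data.frame(replicate_id = r, phase = phase, time_h = times,
                 tissue = tissue, pigmentation = pigmentation,
                 conc_mg_per_kg = apply_noise(true_conc, noise))
    }))
  }
  rows <- with_seed(noise$seed, {
    if (inherits(params, "multi_compartment_params")) {
      stopifnot(inherits(body, "body_composition"))
      sim <- simulate_multi_compartment(params, scenario, times)
      whole <- combine_whole_body(sim$eyes, sim$rest, body)
      rbind(one_series(sim$eyes, "eyes"), one_series(whole, "whole"))
    } else if (inherits(params, "one_compartment_params")) {
      one_series(simulate_one_compartment(params, scenario, times), "whole")
    } else {
      stop_invalid("`params` must be one- or multi-compartment parameters")
    }
  })
  timecourse(rows)
}

#' Generate a synthetic tissue/pigmentation panel
#'
#' Group means are the tissue mean divided by the pigmentation line's fold
#' factor; each pool draws independent noise. Emulates the dissected-tissue
#' panels (pools of 16 larvae, a handful of independent experiments).
#'
#' @param tissue_means Named numeric vector, tissue -> mean mg/kg in the
#'   reference line (e.g. `c(eyes = 1694, brain = 263, trunk = 143)`).
#' @param pigmentation_factors Named numeric vector, line -> fold reduction
#'   (reference line has factor 1, e.g. `c(WT = 1, albino = 50)`); all > 0.
#' @param n_pools Pools per (tissue, line) group; positive.
#' @param noise A [noise_model()].
#' @return A [tissue_panel()].
#' @export
gen_tissue_panel <- function(tissue_means, pigmentation_factors = c(WT = 1),
                             n_pools = 3,
                             noise = noise_model(cv = 0.06, seed = 1)) {
  stopifnot(inherits(noise, "noise_model"))
  if (is.null(names(tissue_means)) || any(tissue_means < 0)) {
    stop_invalid("`tissue_means` must be a named vector of non-negative means")
  }
  if (is.null(names(pigmentation_factors)) || any(pigmentation_factors <= 0)) {
    stop_invalid("`pigmentation_factors` must be a named vector of positive folds")
  }
  check_positive(n_pools, "n_pools")
  grid <- expand.grid(tissue = names(tissue_means),
                      pigmentation = names(pigmentation_factors),
                      pool_id = seq_len(n_pools),
                      stringsAsFactors = FALSE)
  true_mean <- tissue_means[grid$tissue] / pigmentation_factors[grid$pigmentation]
  conc <- with_seed(noise$seed, apply_noise(unname(true_mean), noise))
  tissue_panel(data.frame(tissue = grid$tissue, pigmentation = grid$pigmentation,
                          pool_id = grid$pool_id, conc_mg_per_kg = conc))
}

#' Generate synthetic embryo-test outcomes from a response curve
#'
#' Binomial draws at the response probabilities of a four-parameter logistic
#' curve, emulating the embryo acute toxicity test design (a fixed number of
#' embryos per concentration).
#'
#' @param curve A `dose_response_fit` or a list with `bottom`, `top`,
#'   `log_ec50`, `hill_slope`.
#' @param concentrations Exposure concentrations in uM.
#' @param n_per_conc Embryos per concentration; default 10.
#' @param seed Integer seed; required.
#' @param endpoint Endpoint label.
#' @return A [dose_response_data()].
#' @export
gen_zfet_outcomes <- function(curve, concentrations, n_per_conc = 10, seed,
                              endpoint = "lethal") {
  needed <- c("bottom", "top", "log_ec50", "hill_slope")
  if (!all(needed %in% names(curve))) {
    stop_invalid("`curve` must provide ", paste(needed, collapse = ", "))
  }
  check_positive(n_per_conc, "n_per_conc")
  pr <- four_pl(concentrations, curve$bottom, curve$top,
                curve$log_ec50, curve$hill_slope)
  if (any(pr < 0 | pr > 1)) stop_invalid("curve yields response probabilities outside [0, 1]")
  responding <- with_seed(seed, stats::rbinom(length(pr), size = n_per_conc, prob = pr))
  dose_response_data(concentrations, rep(n_per_conc, length(pr)), responding,
                     endpoint = endpoint)
}
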