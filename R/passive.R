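#' Passive-model coefficient set
#'
#' Loads the gill-uptake bioaccumulation coefficients used by
#' [predict_passive_rates()] from a versioned JSON config. The packaged
#' default implements the Arnot-Gobas kinetic formulation: gill uptake
#' efficiency E_W = 1 / (a + b / Kow), mass-specific ventilation scaling
#' with body weight^0.65 and dissolved oxygen, and elimination by the
#' reverse gill route.
#'
#' @param path Path to a coefficients JSON; defaults to the packaged file.
#' @return A list of class `passive_coefficients`.
#' @export
passive_coefficients <- function(path = system.file("extdata", "passive_coefficients.json",
                                                    package = "larvatk")) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  needed <- c("framework_version", "uptake_efficiency", "ventilation", "oxygen_saturation")
  missing <- setdiff(needed, names(cfg))
  if (length(missing)) stop_invalid("passive coefficients missing: ", paste(missing, collapse = ", "))
  structure(cfg, class = "passive_coefficients")
}

#' Larval characteristics for the passive prediction
#'
#' Inputs of the passive-partitioning baseline: the organism is reduced to
#' its lipid fraction (the partitioning phase), wet weight (ventilation
#' scaling) and water temperature (dissolved-oxygen saturation). Defaults
#' describe a 5 dpf zebrafish larva: 360 ug wet weight, 5% lipid, 28 degC.
#'
#' @param lipid_fraction Lipid mass fraction of the body, in (0, 1).
#' @param body_weight_kg Wet weight in kg; default 3.6e-7 (360 ug).
#' @param water_temperature_c Water temperature, degC.
#' @param dissolved_oxygen_mg_per_l Optional dissolved oxygen concentration
#'   (mg/L); when `NULL` it is derived from temperature via the saturation
#'   relation in the coefficient set.
#' @param partition_input `"logP"` (neutral-species partitioning) or
#'   `"logD"` (pH-corrected); with `"logD"`, `ph` is required.
#' @param ph Medium pH, required when `partition_input = "logD"`.
#' @param coefficients A [passive_coefficients()] set.
#' @return A list of class `passive_model_params`.
#' @export
passive_model_params <- function(lipid_fraction = 0.05,
                                 body_weight_kg = 3.6e-7,
                                 water_temperature_c = 28,
                                 dissolved_oxygen_mg_per_l = NULL,
                                 partition_input = c("logP", "logD"),
                                 ph = NULL,
                                 coefficients = passive_coefficients()) {
  check_number(lipid_fraction, "lipid_fraction", lower = 0, upper = 1,
               allow_boundary = FALSE)
  check_positive(body_weight_kg, "body_weight_kg")
  check_number(water_temperature_c, "water_temperature_c", lower = 0, upper = 45)
  partition_input <- match.arg(partition_input)
  if (partition_input == "logD" && is.null(ph)) {
    stop_invalid("`ph` must be supplied when partition_input = \"logD\"")
  }
  if (!is.null(dissolved_oxygen_mg_per_l)) {
    check_positive(dissolved_oxygen_mg_per_l, "dissolved_oxygen_mg_per_l")
  }
  stopifnot(inherits(coefficients, "passive_coefficients"))
  structure(
    list(lipid_fraction = lipid_fraction, body_weight_kg = body_weight_kg,
         water_temperature_c = water_temperature_c,
         dissolved_oxygen_mg_per_l = dissolved_oxygen_mg_per_l,
         partition_input = partition_input, ph = ph,
         coefficients = coefficients),
    class = "passive_model_params"
  )
}

#' Predict uptake/elimination rate constants from physico-chemical properties
#'
#' The passive baseline: no fitting, only the compound's partition
#' coefficient and the larva's characteristics. Gill uptake efficiency
#' E_W = 1/(a + b/Kow); ventilation G_V = coef x W^exp / C_OX (L/d);
#' k_in = E_W G_V / W (per day, converted to L kg^-1 h^-1); elimination by
#' the reverse route, k_out = k_in / (lipid_fraction x Kow), so the implied
#' steady-state BCF is exactly lipid_fraction x Kow. The measured-vs-
#' predicted gap of this baseline is what quantifies the contribution of
#' active transport and melanin binding.
#'
#' @param compound A [compound()].
#' @param params A [passive_model_params()].
#' @return A [one_compartment_params()] with the predicted rates (no SEs).
#' @examples
#' mcpp <- compound("mCPP", 196.68, 2.06, 8.87)
#' p <- predict_passive_rates(mcpp, passive_model_params())
#' compute_bcf(p$k_in, p$k_out) # lipid_fraction x Kow = 5.74 L/kg
#' @export
predict_passive_rates <- function(compound, params = passive_model_params()) {
  stopifnot(inherits(compound, "compound"), inherits(params, "passive_model_params"))
  cf <- params$coefficients
  log_kow <- if (params$partition_input == "logD") {
    log_d(compound, params$ph)
  } else {
    compound$log_p
  }
  kow <- 10^log_kow
  e_w <- 1 / (cf$uptake_efficiency$a + cf$uptake_efficiency$b / kow)
  c_ox <- params$dissolved_oxygen_mg_per_l
  if (is.null(c_ox)) {
    ox <- cf$oxygen_saturation
    c_ox <- (ox$slope_mg_per_l_per_c * params$water_temperature_c +
               ox$intercept_mg_per_l) * ox$saturation_fraction
  }
  if (c_ox <= 0) stop_invalid("derived dissolved oxygen is non-positive; check temperature")
  g_v <- cf$ventilation$coefficient_l_per_day *
    params$body_weight_kg^cf$ventilation$weight_exponent / c_ox
  k_in_per_day <- e_w * g_v / params$body_weight_kg
  k_in <- k_in_per_day / 24
  k_out <- k_in / (params$lipid_fraction * kow)
  one_compartment_params(k_in, k_out)
}

#' Predicted passive time course
#'
#' Simulates the one-compartment model under the rates predicted by
#' [predict_passive_rates()] — the concentration curve expected if uptake
#' and elimination were purely passive lipid partitioning.
#'
#' @inheritParams predict_passive_rates
#' @param scenario An [exposure_scenario()].
#' @param times Hours since exposure start; non-negative, sorted.
#' @param method Passed to [simulate_one_compartment()].
#' @return Numeric vector of predicted internal concentrations (mg/kg).
#' @export
predict_passive_timecourse <- function(compound, params = passive_model_params(),
                                       scenario, times,
                                       method = c("closed_form", "ode")) {
  rates <- predict_passive_rates(compound, params)
  simulate_one_compartment(rates, scenario, times, method = match.arg(method))
}
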