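#' Define a compound by its physico-chemical descriptors
#'
#' A compound is described by the three properties that drive all unit
#' conversions and passive-partitioning predictions: molecular weight,
#' octanol-water partition coefficient (logP) and acid dissociation constant
#' (pKa, basic-centre convention for amine drugs such as mCPP).
#'
#' @param name Compound name (character scalar).
#' @param molecular_weight Molecular weight in g/mol; must be positive.
#' @param log_p log10 octanol-water partition coefficient (dimensionless).
#' @param p_ka log10 acid dissociation constant of the basic centre.
#'
#' @return An object of class `compound`.
#' @examples
#' mcpp <- compound("mCPP", molecular_weight = 196.68, log_p = 2.06, p_ka = 8.87)
#' mcpp
#' @export
compound <- function(name, molecular_weight, log_p, p_ka) {
  if (!is.character(name) || length(name) != 1L || is.na(name) || !nzchar(name)) {
    stop_invalid("`name` must be a non-empty character scalar")
  }
  check_positive(molecular_weight, "molecular_weight")
  check_number(log_p, "log_p")
  check_number(p_ka, "p_ka")
  structure(
    list(name = name, molecular_weight = molecular_weight,
         log_p = log_p, p_ka = p_ka),
    class = "compound"
  )
}

#' @export
print.compound <- function(x, ...) {
  cat("<compound>", x$name, "\n")
  cat(sprintf("  MW   %.2f g/mol\n", x$molecular_weight))
  cat(sprintf("  logP %.2f\n", x$log_p))
  cat(sprintf("  pKa  %.2f\n", x$p_ka))
  invisible(x)
}

#' Read a compound definition from a JSON config file
#'
#' Expects keys `name`, `molecular_weight`, `log_p`, `p_ka`; unknown keys are
#' rejected so that typos in config files fail loudly.
#'
#' @param path Path to a JSON file.
#' @return A [compound()] object.
#' @export
read_compound <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  wanted <- c("name", "molecular_weight", "log_p", "p_ka")
  extra <- setdiff(names(cfg), wanted)
  if (length(extra)) stop_invalid("unknown compound config keys: ", paste(extra, collapse = ", "))
  missing <- setdiff(wanted, names(cfg))
  if (length(missing)) stop_invalid("missing compound config keys: ", paste(missing, collapse = ", "))
  compound(cfg$name, cfg$molecular_weight, cfg$log_p, cfg$p_ka)
}

#' Convert a molar water concentration to mg/L
#'
#' The canonical water-concentration unit is mg/L (the unit of the uptake
#' forcing function C_w(t)); exposure concentrations are usually stated in
#' micromolar. Conversion is exact: mg/L = uM x MW / 1000.
#'
#' @param conc_um Concentration in micromolar; non-negative, vectorised.
#' @param compound A [compound()].
#' @return Concentration in mg/L at full precision.
#' @examples
#' mcpp <- compound("mCPP", 196.68, 2.06, 8.87)
#' micromolar_to_mg_per_l(5, mcpp) # 0.9834
#' @export
micromolar_to_mg_per_l <- function(conc_um, compound) {
  stopifnot(inherits(compound, "compound"))
  if (!is.numeric(conc_um) || anyNA(conc_um)) stop_invalid("`conc_um` must be numeric")
  if (any(conc_um < 0)) stop_invalid("`conc_um` must be non-negative")
  conc_um * compound$molecular_weight / 1000
}

#' Convert a water concentration in mg/L back to micromolar
#'
#' Exact inverse of [micromolar_to_mg_per_l()].
#'
#' @inheritParams micromolar_to_mg_per_l
#' @param conc_mg_per_l Concentration in mg/L; non-negative, vectorised.
#' @return Concentration in micromolar.
#' @export
mg_per_l_to_micromolar <- function(conc_mg_per_l, compound) {
  stopifnot(inherits(compound, "compound"))
  if (!is.numeric(conc_mg_per_l) || anyNA(conc_mg_per_l)) stop_invalid("`conc_mg_per_l` must be numeric")
  if (any(conc_mg_per_l < 0)) stop_invalid("`conc_mg_per_l` must be non-negative")
  conc_mg_per_l * 1000 / compound$molecular_weight
}

#' Internal concentration from measured amount and wet weight
#'
#' Whole-larva internal concentrations are computed from the drug amount
#' quantified in a homogenate (ng) and the larval wet weight (ug); the
#' canonical internal unit is mg/kg wet weight, numerically equal to ng/mg
#' and to 1000 x ng/ug.
#'
#' @param amount_ng Drug amount in ng; non-negative, vectorised.
#' @param wet_weight_ug Wet weight in ug; must be positive.
#' @return Internal concentration in mg/kg wet weight.
#' @examples
#' amount_to_internal_concentration(110.9, 360) # ~308 mg/kg
#' @export
amount_to_internal_concentration <- function(amount_ng, wet_weight_ug) {
  check_positive(wet_weight_ug, "wet_weight_ug")
  if (!is.numeric(amount_ng) || anyNA(amount_ng)) stop_invalid("`amount_ng` must be numeric")
  if (any(amount_ng < 0)) stop_invalid("`amount_ng` must be non-negative")
  amount_ng / wet_weight_ug * 1000
}

#' Internal-concentration unit views
#'
#' Derived views of the canonical mg/kg wet-weight unit: ng/ug
#' (1 mg/kg = 0.001 ng/ug) and mmol/kg via the molecular weight.
#'
#' @param conc_mg_per_kg Internal concentration in mg/kg; non-negative.
#' @param compound A [compound()] (needed for the molar view only).
#' @return Converted concentration.
#' @export
mg_per_kg_to_ng_per_ug <- function(conc_mg_per_kg) {
  if (!is.numeric(conc_mg_per_kg) || anyNA(conc_mg_per_kg)) stop_invalid("`conc_mg_per_kg` must be numeric")
  if (any(conc_mg_per_kg < 0)) stop_invalid("`conc_mg_per_kg` must be non-negative")
  conc_mg_per_kg / 1000
}

#' @rdname mg_per_kg_to_ng_per_ug
#' @export
mg_per_kg_to_mmol_per_kg <- function(conc_mg_per_kg, compound) {
  stopifnot(inherits(compound, "compound"))
  if (!is.numeric(conc_mg_per_kg) || anyNA(conc_mg_per_kg)) stop_invalid("`conc_mg_per_kg` must be numeric")
  if (any(conc_mg_per_kg < 0)) stop_invalid("`conc_mg_per_kg` must be non-negative")
  conc_mg_per_kg / compound$molecular_weight
}

#' pH-corrected distribution coefficient (logD) for a monoprotic base
#'
#' For an ionisable base only the neutral fraction partitions into octanol;
#' the Henderson-Hasselbalch correction gives
#' logD = logP - log10(1 + 10^(pKa - pH)). The medium pH is always an
#' explicit argument: there is no biologically privileged default and results
#' are sensitive to it (for mCPP, logD is 0.58 at pH 7.4 but 0.91 at pH 7.75).
#'
#' @param compound A [compound()].
#' @param ph Medium pH, strictly inside (0, 14).
#' @return logD (dimensionless), full precision.
#' @examples
#' mcpp <- compound("mCPP", 196.68, 2.06, 8.87)
#' log_d(mcpp, ph = 7.4)
#' @export
log_d <- function(compound, ph) {
  stopifnot(inherits(compound, "compound"))
  check_number(ph, "ph", lower = 0, upper = 14, allow_boundary = FALSE)
  compound$log_p - log10(1 + 10^(compound$p_ka - ph))
}

#' Kinetic bioconcentration factor
#'
#' The steady-state bioconcentration factor of a first-order one-compartment
#' model is the ratio of the uptake and elimination rate constants,
#' BCF = k_in / k_out (L/kg).
#'
#' @param k_in Uptake rate constant, L kg^-1 h^-1; positive.
#' @param k_out Elimination rate constant, h^-1; positive.
#' @return An object of class `bcf_result` with elements `bcf` (L/kg) and
#'   `log_bcf` (log10).
#' @examples
#' compute_bcf(112.9, 0.25) # logBCF 2.65
#' @export
compute_bcf <- function(k_in, k_out) {
  check_positive(k_in, "k_in")
  check_positive(k_out, "k_out")
  bcf <- k_in / k_out
  structure(list(bcf = bcf, log_bcf = log10(bcf)), class = "bcf_result")
}

#' @export
print.bcf_result <- function(x, ...) {
  cat(sprintf("BCF %.4g L/kg (logBCF %.3f)\n", x$bcf, x$log_bcf))
  invisible(x)
}
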