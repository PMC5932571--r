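#' Multi-compartment (eye / rest-of-body) rate constants
#'
#' Parameters of the two-compartment model in which the melanin-rich eye is a
#' separate compartment from the rest of the body. Each compartment exchanges
#' only with the water (no eye-body flux term):
#' dC_eyes/dt = k_in_eyes C_w(t) - k_out_eyes C_eyes(t), and likewise for the
#' rest compartment.
#'
#' @param k_in_eyes,k_in_rest Uptake rate constants, L kg^-1 h^-1; positive.
#' @param k_out_eyes,k_out_rest Elimination rate constants, h^-1; positive.
#' @param se Optional named numeric vector of standard errors with names
#'   among `k_in_eyes`, `k_out_eyes`, `k_in_rest`, `k_out_rest`.
#' @return An object of class `multi_compartment_params`.
#' @examples
#' multi_compartment_params(k_in_eyes = 325, k_out_eyes = 0.05,
#'                          k_in_rest = 143.2, k_out_rest = 0.8)
#' @export
multi_compartment_params <- function(k_in_eyes, k_out_eyes, k_in_rest, k_out_rest,
                                     se = NULL) {
  check_positive(k_in_eyes, "k_in_eyes")
  check_positive(k_out_eyes, "k_out_eyes")
  check_positive(k_in_rest, "k_in_rest")
  check_positive(k_out_rest, "k_out_rest")
  nms <- c("k_in_eyes", "k_out_eyes", "k_in_rest", "k_out_rest")
  se_full <- stats::setNames(rep(NA_real_, 4L), nms)
  if (!is.null(se)) {
    bad <- setdiff(names(se), nms)
    if (length(bad)) stop_invalid("unknown SE names: ", paste(bad, collapse = ", "))
    if (any(se < 0, na.rm = TRUE)) stop_invalid("standard errors must be non-negative")
    se_full[names(se)] <- se
  }
  structure(
    list(k_in_eyes = k_in_eyes, k_out_eyes = k_out_eyes,
         k_in_rest = k_in_rest, k_out_rest = k_out_rest, se = se_full),
    class = "multi_compartment_params"
  )
}

#' @export
print.multi_compartment_params <- function(x, ...) {
  cat("<multi_compartment_params>\n")
  fmt <- function(nm, unit) {
    se <- x$se[[nm]]
    if (is.na(se)) sprintf("  %-10s %.4g %s\n", nm, x[[nm]], unit)
    else sprintf("  %-10s %.4g ± %.2g %s\n", nm, x[[nm]], se, unit)
  }
  cat(fmt("k_in_eyes", "L kg^-1 h^-1"), fmt("k_out_eyes", "h^-1"),
      fmt("k_in_rest", "L kg^-1 h^-1"), fmt("k_out_rest", "h^-1"), sep = "")
  invisible(x)
}

#' Body composition of a larva
#'
#' Splits the larval wet weight into the eye compartment and the rest of the
#' body; the whole-body concentration is the weight-weighted mean of the two
#' compartment concentrations.
#'
#' @param larva_weight_ug Whole-larva wet weight in micrograms; default 360
#'   (the mean 5-7 dpf larval weight used to compute internal concentrations).
#' @param eye_mass_fraction Fraction of body weight in the eyes, in (0, 1);
#'   default 0.10.
#' @return An object of class `body_composition` with `w_eyes` and `w_rest`
#'   in kg and `eye_mass_fraction`.
#' @export
body_composition <- function(larva_weight_ug = 360, eye_mass_fraction = 0.10) {
  check_positive(larva_weight_ug, "larva_weight_ug")
  check_number(eye_mass_fraction, "eye_mass_fraction", lower = 0, upper = 1,
               allow_boundary = FALSE)
  w_total <- larva_weight_ug * 1e-9  # ug -> kg
  structure(
    list(w_eyes = w_total * eye_mass_fraction,
         w_rest = w_total * (1 - eye_mass_fraction),
         eye_mass_fraction = eye_mass_fraction),
    class = "body_composition"
  )
}

#' @export
print.body_composition <- function(x, ...) {
  cat(sprintf("<body_composition> %.3g kg total, eye fraction %.3g\n",
              x$w_eyes + x$w_rest, x$eye_mass_fraction))
  invisible(x)
}

#' Simulate the eye / rest-of-body model
#'
#' Each compartment follows its own first-order uptake-elimination equation
#' under the shared water forcing; solutions are therefore the
#' one-compartment solutions applied per compartment.
#'
#' @param params A [multi_compartment_params()].
#' @param scenario An [exposure_scenario()].
#' @param times Hours since exposure start; non-negative, sorted.
#' @param method `"closed_form"` (default) or `"ode"`.
#' @return A data.frame with columns `time_h`, `eyes`, `rest` (mg/kg).
#' @export
simulate_multi_compartment <- function(params, scenario, times,
                                       method = c("closed_form", "ode")) {
  stopifnot(inherits(params, "multi_compartment_params"),
            inherits(scenario, "exposure_scenario"))
  check_times(times)
  method <- match.arg(method)
  solver <- if (method == "closed_form") one_comp_closed_form else one_comp_ode
  data.frame(
    time_h = times,
    eyes = solver(params$k_in_eyes, params$k_out_eyes, scenario, times),
    rest = solver(params$k_in_rest, params$k_out_rest, scenario, times)
  )
}

#' Weight-weighted whole-body concentration
#'
#' Combines compartment concentrations into the whole-larva concentration:
#' C_larvae = (C_eyes W_eyes + C_rest W_rest) / (W_eyes + W_rest).
#' This conserves chemical mass: the whole-body amount equals the sum of the
#' compartment amounts.
#'
#' @param c_eyes,c_rest Compartment concentrations in mg/kg (vectorised).
#' @param body A [body_composition()].
#' @return Whole-body concentration in mg/kg.
#' @examples
#' combine_whole_body(1694, 143, body_composition(360, 0.10))
#' @export
combine_whole_body <- function(c_eyes, c_rest, body) {
  stopifnot(inherits(body, "body_composition"))
  if (any(c_eyes < 0) || any(c_rest < 0)) stop_invalid("concentrations must be non-negative")
  w_tot <- body$w_eyes + body$w_rest
  if (w_tot <= 0) stop_invalid("total body weight must be positive")
  (c_eyes * body$w_eyes + c_rest * body$w_rest) / w_tot
}

#' Fit the eye / rest-of-body model jointly
#'
#' Joint least squares on the eye time course and the whole-body time course,
#' the latter predicted by weight-combining the two simulated compartments.
#' Eye and whole-body residuals are weighted equally on the concentration
#' scale by default; `weights` rescales the two residual blocks. Standard
#' errors come from the Jacobian at the Levenberg-Marquardt optimum.
#'
#' @param whole_body A [timecourse()] with `tissue == "whole"` rows.
#' @param eyes A [timecourse()] with `tissue == "eyes"` rows (>= 2 time
#'   points required).
#' @param body A [body_composition()].
#' @param scenario The shared [exposure_scenario()].
#' @param weights Length-2 numeric `(eyes, whole)` residual weights.
#' @return An object of class `multi_compartment_fit` with elements `params`
#'   (a [multi_compartment_params()] with SEs), `residuals`, `converged`,
#'   `data`, and the `nls.lm` object.
#' @export
fit_multi_compartment <- function(whole_body, eyes, body, scenario,
                                  weights = c(1, 1)) {
  stopifnot(inherits(body, "body_composition"),
            inherits(scenario, "exposure_scenario"))
  obs_whole <- pool_series(whole_body, tissue = "whole")
  obs_eyes <- pool_series(eyes, tissue = "eyes")
  if (nrow(obs_eyes) < 2L) {
    stop_invalid("multi-compartment fit needs eye data at >= 2 time points; ",
                 "with whole-body data only, use fit_one_compartment()")
  }
  if (nrow(obs_whole) < 2L) stop_invalid("whole-body series too short to fit")
  if (max(obs_whole$time_h, obs_eyes$time_h) > scenario$t_uptake + scenario$t_depuration) {
    stop_invalid("observations extend beyond the exposure scenario window; ",
                 "eye and whole-body series must share the scenario")
  }
  start_eyes <- one_comp_starts(obs_eyes, scenario)
  start_whole <- one_comp_starts(obs_whole, scenario)
  start <- log(c(k_in_eyes = unname(start_eyes["k_in"]),
                 k_out_eyes = unname(start_eyes["k_out"]),
                 k_in_rest = unname(start_whole["k_in"]),
                 k_out_rest = unname(start_whole["k_out"])))
  resid_fn <- function(lp) {
    p <- exp(lp)
    pred_eyes <- one_comp_closed_form(p[1L], p[2L], scenario, obs_eyes$time_h)
    c_eyes_w <- one_comp_closed_form(p[1L], p[2L], scenario, obs_whole$time_h)
    c_rest_w <- one_comp_closed_form(p[3L], p[4L], scenario, obs_whole$time_h)
    pred_whole <- combine_whole_body(c_eyes_w, c_rest_w, body)
    c(weights[1L] * (obs_eyes$conc - pred_eyes),
      weights[2L] * (obs_whole$conc - pred_whole))
  }
  fit <- minpack.lm::nls.lm(par = start, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  if (fit$info < 1 || fit$info > 4) {
    stop_invalid("multi-compartment fit failed to converge: ", fit$message)
  }
  est <- exp(fit$par)
  # delta method back from the log-parameter scale: se(k) = k * se(log k)
  se_log <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                     error = function(e) rep(NA_real_, length(est)))
  se <- stats::setNames(est * se_log, names(est))
  structure(
    list(
      params = multi_compartment_params(est[["k_in_eyes"]], est[["k_out_eyes"]],
                                        est[["k_in_rest"]], est[["k_out_rest"]],
                                        se = se),
      residuals = fit$fvec,
      converged = TRUE,
      data = list(eyes = obs_eyes, whole = obs_whole),
      body = body,
      scenario = scenario,
      nls = fit
    ),
    class = "multi_compartment_fit"
  )
}

#' @export
print.multi_compartment_fit <- function(x, ...) {
  cat("Multi-compartment (eyes / rest-of-body) toxicokinetic fit\n")
  print(x$params)
  hl <- compartment_half_lives(x$params)
  cat(sprintf("  elimination half-lives: eyes %.3g h, rest %.3g h; RSS %.4g\n",
              hl[["eyes"]], hl[["rest"]], sum(x$residuals^2)))
  invisible(x)
}

#' Elimination half-lives per compartment
#'
#' First-order elimination half-life t1/2 = ln(2) / k_out for each
#' compartment.
#'
#' @param params A [multi_compartment_params()] or [one_compartment_params()].
#' @return Named numeric vector of half-lives in hours.
#' @examples
#' p <- multi_compartment_params(325, 0.05, 143.2, 0.8)
#' compartment_half_lives(p) # eyes ~13.9 h, rest ~0.87 h
#' @export
compartment_half_lives <- function(params) {
  if (inherits(params, "one_compartment_params")) {
    return(c(whole = log(2) / params$k_out))
  }
  stopifnot(inherits(params, "multi_compartment_params"))
  c(eyes = log(2) / params$k_out_eyes, rest = log(2) / params$k_out_rest)
}
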