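#' Dose-response outcome table
#'
#' Binary endpoint counts per exposure concentration from an embryo acute
#' toxicity test: at each concentration, the number of embryos exposed and
#' the number showing the endpoint (lethal or sub-lethal).
#'
#' @param conc_um Exposure concentrations in uM; non-negative, distinct.
#' @param n_exposed Embryos exposed per concentration; positive integers.
#' @param n_responding Embryos responding; `0 <= n_responding <= n_exposed`.
#' @param endpoint Endpoint label, e.g. `"lethal"` or `"sublethal"`.
#' @return A data.frame of class `dose_response_data` with an added
#'   `response` column (observed proportion).
#' @export
dose_response_data <- function(conc_um, n_exposed, n_responding,
                               endpoint = "lethal") {
  if (anyNA(conc_um) || any(conc_um < 0)) stop_invalid("concentrations must be non-negative")
  if (anyDuplicated(conc_um)) stop_invalid("concentrations must be distinct")
  if (length(n_exposed) != length(conc_um) || length(n_responding) != length(conc_um)) {
    stop_invalid("conc_um, n_exposed and n_responding must have equal length")
  }
  if (any(n_exposed <= 0)) stop_invalid("n_exposed must be positive")
  if (any(n_responding < 0 | n_responding > n_exposed)) {
    stop_invalid("n_responding must be between 0 and n_exposed")
  }
  out <- data.frame(conc_um = conc_um, n_exposed = n_exposed,
                    n_responding = n_responding,
                    response = n_responding / n_exposed,
                    endpoint = endpoint)
  out <- out[order(out$conc_um), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("dose_response_data", "data.frame")
  out
}

#' Four-parameter logistic (variable-slope) response curve
#'
#' `response = bottom + (top - bottom) / (1 + 10^((log_ec50 - log10(conc)) * hill))`.
#'
#' @param conc_um Concentrations in uM (positive; 0 maps to the bottom asymptote).
#' @param bottom,top Lower and upper response asymptotes (fractions).
#' @param log_ec50 log10 of the half-maximal concentration (log10 uM).
#' @param hill Hill slope (dimensionless).
#' @return Response fractions.
#' @export
four_pl <- function(conc_um, bottom, top, log_ec50, hill) {
  resp <- ifelse(conc_um <= 0,
                 if (hill > 0) bottom else top,
                 bottom + (top - bottom) / (1 + 10^((log_ec50 - log10(pmax(conc_um, .Machine$double.xmin))) * hill)))
  resp
}

#' Fit the four-parameter logistic dose-response model
#'
#' Least-squares fit of the variable-slope sigmoid to observed response
#' proportions (the convention of standard dose-response software);
#' `method = "binomial"` instead maximises the binomial likelihood.
#' EC50 confidence limits come from the SE of log_ec50 (normal
#' approximation on the log scale; profile likelihood is out of scope).
#' Data that are all-0% or all-100% carry no location information and are
#' flagged non-estimable.
#'
#' @param data A [dose_response_data()].
#' @param method `"ls"` (default) or `"binomial"`.
#' @param fix_bottom,fix_top Optionally fix an asymptote (e.g. 0 and 1).
#' @return An object of class `dose_response_fit` with `bottom`, `top`,
#'   `log_ec50`, `hill_slope`, `ec50`, `ec50_ci` (95%), `se`, `converged`,
#'   `warnings`.
#' @export
fit_4pl <- function(data, method = c("ls", "binomial"),
                    fix_bottom = NULL, fix_top = NULL) {
  stopifnot(inherits(data, "dose_response_data"))
  method <- match.arg(method)
  d <- data[data$conc_um > 0, , drop = FALSE]
  if (nrow(d) < 4L) stop_invalid("4PL fit needs >= 4 distinct positive concentrations")
  if (all(d$response == 0) || all(d$response == 1)) {
    stop_invalid("non-estimable: all responses at the same extreme (no partial responses)")
  }
  warnings <- character()
  logc <- log10(d$conc_um)
  # starts: asymptotes from data range, EC50 from the concentration nearest
  # the half response, hill from a coarse logit-slope
  b0 <- if (is.null(fix_bottom)) min(d$response) else fix_bottom
  t0 <- if (is.null(fix_top)) max(d$response) else fix_top
  half <- (b0 + t0) / 2
  le0 <- logc[which.min(abs(d$response - half))]
  start <- list(log_ec50 = le0, hill = 1)
  if (is.null(fix_bottom)) start$bottom <- b0
  if (is.null(fix_top)) start$top <- t0
  model_resp <- function(p) {
    four_pl(d$conc_um,
            bottom = if (is.null(fix_bottom)) p[["bottom"]] else fix_bottom,
            top = if (is.null(fix_top)) p[["top"]] else fix_top,
            log_ec50 = p[["log_ec50"]], hill = p[["hill"]])
  }
  if (method == "ls") {
    resid_fn <- function(p) d$response - model_resp(p)
  } else {
    eps <- 1e-9
    resid_fn <- function(p) {
      pr <- pmin(pmax(model_resp(p), eps), 1 - eps)
      # signed sqrt deviance residuals -> LM minimises binomial deviance
      dev <- -2 * (d$n_responding * log(pr) + (d$n_exposed - d$n_responding) * log(1 - pr)) +
        2 * ifelse(d$response %in% c(0, 1), 0,
                   d$n_responding * log(d$response) +
                     (d$n_exposed - d$n_responding) * log(1 - d$response))
      sign(d$response - pr) * sqrt(pmax(dev, 0))
    }
  }
  fit <- minpack.lm::nls.lm(par = unlist(start), fn = resid_fn,
                            control = minpack.lm::nls.lm.control(maxiter = 1000,
                                                                 maxfev = 10000))
  conv <- fit$info >= 1 && fit$info <= 4
  if (!conv) warnings <- c(warnings, paste("convergence not reached:", fit$message))
  p <- fit$par
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) stats::setNames(rep(NA_real_, length(p)), names(p)))
  log_ec50 <- p[["log_ec50"]]
  ec50 <- 10^log_ec50
  ci <- 10^(log_ec50 + c(-1, 1) * 1.96 * se[["log_ec50"]])
  # CI spanning more than two decades: location is essentially undetermined
  if (any(!is.finite(se)) || ci[2L] / ci[1L] > 100) {
    warnings <- c(warnings, "EC50 poorly determined (wide confidence interval)")
  }
  bottom <- if (is.null(fix_bottom)) p[["bottom"]] else fix_bottom
  top <- if (is.null(fix_top)) p[["top"]] else fix_top
  if (bottom > top) warnings <- c(warnings, "fitted bottom exceeds top (inverted curve)")
  if (length(warnings)) for (w in warnings) warning(w, call. = FALSE)
  structure(
    list(bottom = bottom, top = top, log_ec50 = log_ec50,
         hill_slope = p[["hill"]], ec50 = ec50,
         ec50_ci = stats::setNames(ci, c("lower", "upper")),
         se = se, converged = conv, warnings = warnings,
         endpoint = data$endpoint[1L], method = method, nls = fit),
    class = "dose_response_fit"
  )
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("4PL dose-response fit (%s endpoint, %s)\n", x$endpoint, x$method))
  cat(sprintf("  EC50 %.4g uM (95%% CI %.3g-%.3g), hill %.3g, bottom %.3g, top %.3g\n",
              x$ec50, x$ec50_ci[["lower"]], x$ec50_ci[["upper"]],
              x$hill_slope, x$bottom, x$top))
  invisible(x)
}

#' Internal-dose metric from an external effect concentration
#'
#' Converts an external (water) effect concentration to an internal molar
#' body burden via the bioconcentration factor:
#' internal dose (mmol/kg) = external concentration (mmol/L) x BCF (L/kg).
#' This is the approximation used for ILC50/IEC50/INTC analogues; outputs
#' are labelled approximate. The conversion is molar-to-molar, so the
#' compound's molecular weight cancels and is not needed.
#'
#' @param external_conc_um External concentration in uM; positive.
#' @param bcf Bioconcentration factor in L/kg; positive. Either a number or
#'   a `bcf_result` from [compute_bcf()].
#' @return Internal dose in mmol/kg, with attribute `approximate = TRUE`.
#' @examples
#' internal_dose_metric(100, compute_bcf(112.9, 0.25))
#' @export
internal_dose_metric <- function(external_conc_um, bcf) {
  if (inherits(bcf, "bcf_result")) bcf <- bcf$bcf
  check_positive(bcf, "bcf")
  if (any(external_conc_um <= 0)) stop_invalid("`external_conc_um` must be positive")
  out <- external_conc_um * 1e-3 * bcf  # uM -> mmol/L, x L/kg
  attr(out, "approximate") <- TRUE
  out
}
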