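#' Exposure scenario: constant bath then clean water
#'
#' Encodes the forcing function C_w(t): the water concentration is treated as
#' constant at `c_w` from time 0 to `t_uptake` (daily-renewal exposure over a
#' short window, with bath volume far exceeding larval mass so larval uptake
#' does not deplete the bath) and exactly 0 afterwards, for `t_depuration`
#' hours of depuration in clean medium.
#'
#' @param c_w Water concentration during uptake, mg/L; non-negative.
#' @param t_uptake Uptake duration in hours; positive.
#' @param t_depuration Depuration duration in hours; non-negative.
#' @return An object of class `exposure_scenario`.
#' @examples
#' # 5 uM mCPP (0.9834 mg/L) for 8 h, then 48 h clean water
#' exposure_scenario(c_w = 0.9834, t_uptake = 8, t_depuration = 48)
#' @export
exposure_scenario <- function(c_w, t_uptake, t_depuration = 0) {
  check_non_negative(c_w, "c_w")
  check_positive(t_uptake, "t_uptake")
  check_non_negative(t_depuration, "t_depuration")
  structure(
    list(c_w = c_w, t_uptake = t_uptake, t_depuration = t_depuration),
    class = "exposure_scenario"
  )
}

#' @export
print.exposure_scenario <- function(x, ...) {
  cat(sprintf("<exposure_scenario> %.4g mg/L for %g h uptake, %g h depuration\n",
              x$c_w, x$t_uptake, x$t_depuration))
  invisible(x)
}

#' Water concentration at given times
#'
#' Evaluates the forcing function C_w(t) of an [exposure_scenario()]:
#' `c_w` for t <= t_uptake, 0 afterwards.
#'
#' @param scenario An [exposure_scenario()].
#' @param times Hours since exposure start; non-negative.
#' @return Numeric vector of water concentrations (mg/L).
#' @export
water_conc <- function(scenario, times) {
  stopifnot(inherits(scenario, "exposure_scenario"))
  ifelse(times <= scenario$t_uptake, scenario$c_w, 0)
}

#' Default sampling grids
#'
#' The sampling designs the analyses assume: uptake sampling at
#' 0.25, 1, 3, 6, 8 and 10 h of exposure and depuration sampling at
#' 1, 3, 6, 18, 24, 27 and 48 h after transfer to clean water.
#' `default_depuration_times()` returns times since depuration start; add
#' `t_uptake` to place them on the absolute axis.
#'
#' @return Numeric vector of hours.
#' @export
default_uptake_times <- function() c(0.25, 1, 3, 6, 8, 10)

#' @rdname default_uptake_times
#' @export
default_depuration_times <- function() c(1, 3, 6, 18, 24, 27, 48)
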