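#' Biphasic depuration half-lives by two-segment log-linear regression
#'
#' Depuration of chemicals bound in a slowly releasing reservoir (here,
#' melanin in the eye) is biphasic: a fast initial and a slow terminal
#' exponential phase. The estimator fits two log-linear segments to
#' ln(concentration) versus time since depuration start, scanning every
#' interior observed time point as a candidate breakpoint (an exhaustive
#' scan, so the chosen breakpoint is SSE-optimal by construction). The
#' breakpoint observation belongs to both segments; ties in SSE break toward
#' the earlier breakpoint. Each segment's half-life is ln(2)/|slope|.
#'
#' Replicates are pooled to per-time means before regression by default.
#' Non-positive concentrations cannot enter a log regression and are dropped
#' with a warning. When the two slopes are essentially equal the data are
#' single-exponential and the estimate is flagged degenerate.
#'
#' @param data A [timecourse()] (depuration rows are used), or any data.frame
#'   with `time_h` and `conc_mg_per_kg` columns.
#' @param depuration_start Hours to subtract from `time_h` so that the
#'   depuration phase starts at 0 (pass the scenario's `t_uptake` when times
#'   are on the absolute axis); default 0.
#' @param tissue Tissue series to use when `data` is a [timecourse()].
#' @param pooled Pool replicates to per-time means (default) or use all rows.
#' @param degeneracy_tol Relative slope difference below which the two
#'   phases are flagged as indistinguishable; default 0.05.
#' @return An object of class `half_life_estimate`: initial and terminal
#'   half-lives (h), breakpoint (h since depuration start), per-phase slopes
#'   with standard errors, points per phase, and a `degenerate` flag.
#' @export
biphasic_half_lives <- function(data, depuration_start = 0, tissue = "whole",
                                pooled = TRUE, degeneracy_tol = 0.05) {
  if (inherits(data, "timecourse")) {
    obs <- if (pooled) {
      pool_series(data, tissue = tissue, phase = "depuration")
    } else {
      d <- data[data$tissue == tissue & data$phase == "depuration", , drop = FALSE]
      data.frame(time_h = d$time_h, conc = d$conc_mg_per_kg)
    }
  } else {
    if (!all(c("time_h", "conc_mg_per_kg") %in% names(data))) {
      stop_invalid("`data` must be a timecourse or have time_h and conc_mg_per_kg columns")
    }
    obs <- data.frame(time_h = data$time_h, conc = data$conc_mg_per_kg)
    if (pooled) {
      obs <- stats::aggregate(conc ~ time_h, data = obs, FUN = mean)
    }
  }
  obs$time_h <- obs$time_h - depuration_start
  if (any(obs$time_h < 0)) stop_invalid("negative depuration times after rebasing; check `depuration_start`")
  nonpos <- obs$conc <= 0
  if (any(nonpos)) {
    warning(sum(nonpos), " non-positive concentration(s) dropped from log-linear regression")
    obs <- obs[!nonpos, , drop = FALSE]
  }
  obs <- obs[order(obs$time_h), , drop = FALSE]
  times <- unique(obs$time_h)
  if (length(times) < 4L) {
    stop_invalid("biphasic half-life estimation needs >= 4 depuration time points ",
                 "with positive concentration (got ", length(times), ")")
  }
  seg_fit <- function(d) stats::lm(log(conc) ~ time_h, data = d)
  # interior breakpoints only: each segment keeps >= 2 points
  candidates <- times[-c(1L, length(times))]
  best <- NULL
  for (bp in candidates) {
    f1 <- seg_fit(obs[obs$time_h <= bp, , drop = FALSE])
    f2 <- seg_fit(obs[obs$time_h >= bp, , drop = FALSE])
    sse <- sum(stats::residuals(f1)^2) + sum(stats::residuals(f2)^2)
    if (is.null(best) || sse < best$sse - 1e-12) {  # strict: ties keep earlier bp
      best <- list(bp = bp, f1 = f1, f2 = f2, sse = sse)
    }
  }
  slope <- function(f) stats::coef(f)[[2L]]
  # suppress lm's "essentially perfect fit" note on noise-free segments
  slope_se <- function(f) suppressWarnings(summary(f)$coefficients[2L, 2L])
  s1 <- slope(best$f1); s2 <- slope(best$f2)
  if (s1 >= 0 || s2 >= 0) {
    warning("non-decaying segment slope; half-life undefined for that segment")
  }
  degenerate <- abs(s1 - s2) <= degeneracy_tol * max(abs(s1), abs(s2))
  structure(
    list(
      initial_half_life = log(2) / abs(s1),
      terminal_half_life = log(2) / abs(s2),
      breakpoint = best$bp,
      slopes = c(initial = s1, terminal = s2),
      slope_se = c(initial = slope_se(best$f1), terminal = slope_se(best$f2)),
      n_points = c(initial = nrow(best$f1$model), terminal = nrow(best$f2$model)),
      degenerate = degenerate,
      sse = best$sse
    ),
    class = "half_life_estimate"
  )
}

#' @export
print.half_life_estimate <- function(x, ...) {
  cat("Biphasic depuration half-lives (two-segment log-linear)\n")
  cat(sprintf("  initial  t1/2 %.3g h  (%d points)\n",
              x$initial_half_life, x$n_points[["initial"]]))
  cat(sprintf("  terminal t1/2 %.3g h  (%d points)\n",
              x$terminal_half_life, x$n_points[["terminal"]]))
  cat(sprintf("  breakpoint %.3g h after depuration start%s\n", x$breakpoint,
              if (x$degenerate) " [degenerate: single-exponential]" else ""))
  invisible(x)
}

#' Percent of the initial concentration remaining
#'
#' @param c_final Concentration at the end of depuration (mg/kg).
#' @param c_initial Concentration at depuration start (mg/kg); positive.
#' @return Percentage (0-100 scale for complete elimination to none).
#' @examples
#' percent_remaining(134.5, 1694) # eyes after 48 h: ~7.9%
#' @export
percent_remaining <- function(c_final, c_initial) {
  if (any(c_initial <= 0)) stop_invalid("`c_initial` must be positive")
  if (any(c_final < 0)) stop_invalid("`c_final` must be non-negative")
  100 * c_final / c_initial
}

#' Fold difference between a reference and another concentration
#'
#' @param reference Reference concentration (e.g. wild-type mean).
#' @param other Comparison concentration; positive.
#' @return `reference / other` (dimensionless).
#' @examples
#' fold_difference(250, 36) # whole-body WT vs albino: ~6.9-fold
#' @export
fold_difference <- function(reference, other) {
  if (any(other <= 0)) stop_invalid("`other` must be positive")
  if (any(reference < 0)) stop_invalid("`reference` must be non-negative")
  reference / other
}

#' Linear scaling of a tissue concentration across exposure doses
#'
#' Under the assumption of dose-linear uptake, the tissue concentration at a
#' query exposure dose is the measured concentration at a reference dose
#' scaled by the dose ratio.
#'
#' @param c_tissue_at_ref Tissue concentration at the reference dose (any
#'   concentration unit; the result is in the same unit).
#' @param dose_ref Reference exposure dose (uM); positive.
#' @param dose_query Query exposure dose (uM); non-negative.
#' @return Predicted tissue concentration at `dose_query`.
#' @examples
#' # brain 0.3 ng/ug at 5 uM -> predicted level at 0.01 uM
#' linear_dose_scaling(0.3, dose_ref = 5, dose_query = 0.01)
#' @export
linear_dose_scaling <- function(c_tissue_at_ref, dose_ref, dose_query) {
  check_positive(dose_ref, "dose_ref")
  if (any(dose_query < 0)) stop_invalid("`dose_query` must be non-negative")
  if (any(c_tissue_at_ref < 0)) stop_invalid("`c_tissue_at_ref` must be non-negative")
  c_tissue_at_ref * dose_query / dose_ref
}
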