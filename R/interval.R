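#' Reference interval objects
#'
#' A `ref_interval` is a covariate-dependent band `[lower(age, sex),
#' upper(age, sex)]` at miscoverage level `alpha`, intended to contain a
#' healthy observation with probability `1 - alpha` and to miss with
#' probability `alpha/2` in each tail. Naive intervals come from a fitted
#' model ([naive_interval()]); calibrated intervals come from
#' [reform_calibrate()]; intervals can also be rebuilt from a gridded file
#' via [interpolate_interval()].
#'
#' @param alpha miscoverage level in (0, 1).
#' @param lower,upper vectorised functions of `(age, sex)` returning bound
#'   values.
#' @param calibrated logical; has conformal calibration been applied?
#' @param provenance free-text description of the generating model.
#' @param age_range numeric length-2; ages over which the bounds are
#'   considered evaluable (used for probe grids and gridded export).
#' @param sexes character vector of valid sex levels.
#' @param constants optional tibble of calibration constants (see
#'   [reform_calibrate()]).
#' @return an object of class `ref_interval`.
#' @export
new_ref_interval <- function(alpha, lower, upper, calibrated = FALSE,
                             provenance = "unspecified",
                             age_range = c(18, 100), sexes = c("F", "M"),
                             constants = NULL) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    stop_refcal("`alpha` must be a single value in (0, 1).",
                "refcal_domain_error")
  }
  stopifnot(is.function(lower), is.function(upper))
  structure(
    list(
      alpha = alpha, lower = lower, upper = upper,
      calibrated = isTRUE(calibrated), provenance = provenance,
      age_range = as.numeric(age_range), sexes = sexes,
      constants = constants
    ),
    class = "ref_interval"
  )
}

#' Evaluate reference-interval bounds
#'
#' @param interval a `ref_interval`.
#' @param age,sex covariate vectors (recycled to common length).
#' @return tibble with columns `age`, `sex`, `lower`, `upper`.
#' @export
interval_bounds <- function(interval, age, sex) {
  k <- max(length(age), length(sex))
  age <- rep_len(age, k)
  sex <- rep_len(as.character(sex), k)
  check_sex_levels(sex, interval$sexes)
  lo <- interval$lower(age, sex)
  hi <- interval$upper(age, sex)
  bad <- which(!is.finite(lo) | !is.finite(hi))
  # infinite bounds are legal (overflow = "infinite"); NA / NaN are not
  bad <- bad[is.na(lo[bad]) | is.na(hi[bad])]
  if (length(bad) > 0) {
    stop_refcal(
      paste0("Interval not evaluable at age=", age[bad[1]],
             ", sex=", sex[bad[1]], "."),
      "refcal_evaluation_error"
    )
  }
  tibble(age = age, sex = sex, lower = lo, upper = hi)
}

#' @export
print.ref_interval <- function(x, ...) {
  cat(sprintf(
    "%s %.0f%% reference interval (alpha = %g)\n",
    if (x$calibrated) "Calibrated" else "Naive", 100 * (1 - x$alpha), x$alpha
  ))
  cat("  provenance:", x$provenance, "\n")
  if (!is.null(x$constants)) {
    cat(sprintf("  constants: c_lower = %.6g, c_upper = %.6g (nC = %d)\n",
                x$constants$c_lower, x$constants$c_upper, x$constants$n_cal))
  }
  invisible(x)
}

probe_grid <- function(interval, n = 101) {
  expand.grid(
    age = seq(interval$age_range[1], interval$age_range[2], length.out = n),
    sex = interval$sexes, stringsAsFactors = FALSE
  )
}

#' Build a naive reference interval from a fitted model
#'
#' For a location-scale-shape fit, the bounds are the model's conditional
#' BCT quantiles at `alpha/2` and `1 - alpha/2`. For additive quantile
#' regression pass the fitted lower-tail curve as `object` and the fitted
#' upper-tail curve as `upper`; the levels must be `alpha/2` and
#' `1 - alpha/2` for a common `alpha`, otherwise an error is raised.
#' Independently fitted quantile curves may cross; crossings on a probe grid
#' are reported as a warning, not repaired.
#'
#' @param object an `lss_fit` or the lower-tail `aqr_fit`.
#' @param alpha miscoverage level in (0, 1).
#' @param ... passed to methods.
#' @return a `ref_interval` with `calibrated = FALSE`.
#' @export
naive_interval <- function(object, alpha, ...) {
  UseMethod("naive_interval")
}

#' @rdname naive_interval
#' @export
naive_interval.lss_fit <- function(object, alpha, ...) {
  fit <- object
  lower <- function(age, sex) {
    lss_quantile(fit, alpha / 2, tibble(age = age, sex = sex))
  }
  upper <- function(age, sex) {
    lss_quantile(fit, 1 - alpha / 2, tibble(age = age, sex = sex))
  }
  new_ref_interval(
    alpha, lower, upper,
    provenance = sprintf("bct_lss(n=%d, nu=%.3g, tau=%.3g)",
                         fit$n, fit$nu, fit$tau),
    age_range = fit$age_range, sexes = fit$sexes
  )
}

#' @param upper the upper-tail `aqr_fit` (required for the quantile-curve
#'   method).
#' @rdname naive_interval
#' @export
naive_interval.aqr_fit <- function(object, alpha = NULL, upper, ...) {
  if (missing(upper) || !inherits(upper, "aqr_fit")) {
    stop_refcal("Provide the upper-tail `aqr_fit` via `upper`.",
                "refcal_domain_error")
  }
  if (abs(object$tau_level + upper$tau_level - 1) > 1e-8 ||
      object$tau_level >= 0.5) {
    stop_refcal(
      sprintf(paste0(
        "Quantile-curve levels mismatch: lower tau = %g, upper tau = %g ",
        "(need tau and 1 - tau with tau < 0.5)."),
        object$tau_level, upper$tau_level),
      "refcal_level_mismatch"
    )
  }
  implied_alpha <- 2 * object$tau_level
  if (!is.null(alpha) && abs(alpha - implied_alpha) > 1e-8) {
    stop_refcal(
      sprintf("`alpha` (%g) disagrees with the curve levels (imply %g).",
              alpha, implied_alpha),
      "refcal_level_mismatch"
    )
  }
  lo_fit <- object
  hi_fit <- upper
  interval <- new_ref_interval(
    implied_alpha,
    lower = function(age, sex) predict(lo_fit, tibble(age = age, sex = sex)),
    upper = function(age, sex) predict(hi_fit, tibble(age = age, sex = sex)),
    provenance = sprintf("additive_qr(n=%d, tau=%g/%g)",
                         lo_fit$n, lo_fit$tau_level, hi_fit$tau_level),
    age_range = lo_fit$age_range, sexes = lo_fit$sexes
  )
  g <- probe_grid(interval)
  b <- interval_bounds(interval, g$age, g$sex)
  if (any(b$lower > b$upper)) {
    rlang::warn("Fitted quantile curves cross on the probe grid.",
                class = "refcal_crossing_warning")
  }
  interval
}
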