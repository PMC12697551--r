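#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a location-scale-shape fit
#'
#' @param x an `lss_fit`.
#' @param ... unused.
#' @return tibble of coefficients: one row per term with `parameter`
#'   (`mu` / `log_sigma`), `term` and `estimate`.
#' @export
tidy.lss_fit <- function(x, ...) {
  k <- basis_dim(x$basis)
  terms <- c(paste0("spline", seq_len(k)), "sexM")
  dplyr::bind_rows(
    tibble(parameter = "mu", term = terms, estimate = unname(x$coef_mu)),
    tibble(parameter = "log_sigma", term = terms,
           estimate = unname(x$coef_sigma)),
    tibble(parameter = "nu", term = "(constant)", estimate = x$nu),
    tibble(parameter = "tau", term = "(constant)", estimate = x$tau)
  )
}

#' @rdname tidy.lss_fit
#' @export
glance.lss_fit <- function(x, ...) {
  tibble(n = x$n, logLik = x$logLik, objective = x$objective,
         nu = x$nu, tau = x$tau, lambda = x$lambda,
         converged = x$converged, iterations = x$iterations)
}

#' Tidy an additive quantile fit
#'
#' @param x an `aqr_fit`.
#' @param ... unused.
#' @return tibble of spline and sex-offset coefficients.
#' @export
tidy.aqr_fit <- function(x, ...) {
  k <- basis_dim(x$basis)
  tibble(term = c(paste0("spline", seq_len(k)), "sexM"),
         estimate = unname(x$coef))
}

#' @rdname tidy.aqr_fit
#' @export
glance.aqr_fit <- function(x, ...) {
  tibble(n = x$n, tau_level = x$tau_level, lambda = x$lambda,
         objective = utils::tail(x$objective_trace, 1),
         iterations = length(x$objective_trace) - 1,
         converged = x$converged)
}

#' Tidy a reference interval
#'
#' Tabulates the bounds on an age grid (101 points per sex by default), the
#' same grid convention used by the file exchange format.
#'
#' @param x a `ref_interval`.
#' @param n_grid grid resolution.
#' @param ... unused.
#' @return tibble with `sex`, `age`, `lower`, `upper`.
#' @export
tidy.ref_interval <- function(x, n_grid = 101, ...) {
  g <- probe_grid(x, n = n_grid)
  interval_bounds(x, g$age, g$sex)[, c("sex", "age", "lower", "upper")] |>
    dplyr::arrange(.data$sex, .data$age)
}

#' @rdname tidy.ref_interval
#' @export
glance.ref_interval <- function(x, ...) {
  tibble(
    alpha = x$alpha, calibrated = x$calibrated,
    c_lower = if (is.null(x$constants)) NA_real_ else x$constants$c_lower,
    c_upper = if (is.null(x$constants)) NA_real_ else x$constants$c_upper,
    n_cal = if (is.null(x$constants)) NA_integer_ else x$constants$n_cal,
    provenance = x$provenance
  )
}

#' @rdname fit_batch_lss
#' @param x a `batch_lss_fit`.
#' @export
tidy.batch_lss_fit <- function(x, ...) {
  x$offsets
}
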