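#' Serialize a fitted naive model to JSON
#'
#' Writes a JSON document holding everything needed to re-evaluate the
#' model's quantile curves without the training data: basis knots and
#' boundary, coefficient vectors, constant shape parameters and fit
#' metadata. Supports [fit_lss()] and [fit_aqr()] objects.
#'
#' @param fit an `lss_fit` or `aqr_fit`.
#' @param path output file path.
#' @return (invisibly) the path.
#' @export
write_model_json <- function(fit, path) {
  common <- list(
    basis = list(knots = fit$basis$knots, boundary = fit$basis$boundary,
                 degree = fit$basis$degree),
    lambda = fit$lambda, n = fit$n, converged = fit$converged,
    age_range = fit$age_range, sexes = fit$sexes
  )
  doc <- if (inherits(fit, "lss_fit")) {
    c(list(type = "lss_fit", coef_mu = unname(fit$coef_mu),
           coef_sigma = unname(fit$coef_sigma), nu = fit$nu, tau = fit$tau,
           logLik = fit$logLik, objective = fit$objective,
           init_objective = fit$init_objective, iterations = fit$iterations),
      common)
  } else if (inherits(fit, "aqr_fit")) {
    c(list(type = "aqr_fit", coef = unname(fit$coef),
           tau_level = fit$tau_level,
           objective_trace = fit$objective_trace),
      common)
  } else {
    stop_refcal("Unsupported model class.", "refcal_domain_error")
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Rebuild a fitted naive model from its JSON document
#'
#' @param path file written by [write_model_json()].
#' @return an `lss_fit` or `aqr_fit` that evaluates quantiles identically to
#'   the original fit.
#' @export
read_model_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  basis <- structure(
    list(knots = as.numeric(doc$basis$knots),
         boundary = as.numeric(doc$basis$boundary),
         degree = as.integer(doc$basis$degree)),
    class = "refcal_basis"
  )
  if (identical(doc$type, "lss_fit")) {
    structure(
      list(basis = basis, coef_mu = doc$coef_mu, coef_sigma = doc$coef_sigma,
           nu = doc$nu, tau = doc$tau, lambda = doc$lambda, n = doc$n,
           logLik = doc$logLik, objective = doc$objective,
           init_objective = doc$init_objective, converged = doc$converged,
           iterations = doc$iterations, age_range = doc$age_range,
           sexes = doc$sexes),
      class = "lss_fit"
    )
  } else if (identical(doc$type, "aqr_fit")) {
    structure(
      list(basis = basis, coef = doc$coef, tau_level = doc$tau_level,
           lambda = doc$lambda, n = doc$n,
           objective_trace = doc$objective_trace, converged = doc$converged,
           age_range = doc$age_range, sexes = doc$sexes),
      class = "aqr_fit"
    )
  } else {
    stop_refcal(paste0("Unknown model type: ", doc$type, "."),
                "refcal_schema_error")
  }
}
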