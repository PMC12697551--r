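#' The Box-Cox t distribution
#'
#' Density, distribution function, quantile function, and random generation
#' for the four-parameter Box-Cox t (BCT) distribution commonly used for
#' centile modelling of positive-valued phenotypes. The distribution is
#' defined through the transform
#' \deqn{z = \frac{(y/\mu)^\nu - 1}{\nu\sigma} \quad (\nu \neq 0), \qquad
#'       z = \frac{\log(y/\mu)}{\sigma} \quad (\nu = 0),}
#' where \eqn{z} follows a t distribution with \eqn{\tau} degrees of freedom,
#' truncated so that \eqn{Y > 0}. \eqn{\mu > 0} is a location (approximately
#' the median), \eqn{\sigma > 0} a relative scale, \eqn{\nu} a skewness power
#' and \eqn{\tau > 0} the tail degrees of freedom.
#'
#' @param x,q vector of positive quantiles.
#' @param p vector of probabilities in (0, 1).
#' @param n number of draws.
#' @param mu location parameter(s), > 0.
#' @param sigma scale parameter(s), > 0.
#' @param nu skewness power (real scalar or vector).
#' @param tau degrees of freedom, > 0.
#' @param log,log.p logical; return log-density / log-probability.
#'
#' @return `dbct` the density, `pbct` the CDF, `qbct` quantiles (strictly
#'   increasing in `p`), `rbct` random draws. All are vectorised with the
#'   usual recycling rules.
#' @examples
#' qbct(0.5, mu = 3, sigma = 0.05, nu = 1, tau = 10)
#' pbct(qbct(0.9, 3, 0.1, 0.5, 8), 3, 0.1, 0.5, 8)
#' @name bct
NULL

check_bct_params <- function(mu, sigma, tau) {
  if (any(!is.finite(mu)) || any(mu <= 0)) {
    stop_refcal("`mu` must be finite and > 0.", "refcal_domain_error")
  }
  if (any(!is.finite(sigma)) || any(sigma <= 0)) {
    stop_refcal("`sigma` must be finite and > 0.", "refcal_domain_error")
  }
  if (any(!is.finite(tau)) || any(tau <= 0)) {
    stop_refcal("`tau` must be finite and > 0.", "refcal_domain_error")
  }
  invisible(NULL)
}

bct_z <- function(y, mu, sigma, nu) {
  ifelse(abs(nu) > 1e-12,
    ((y / mu)^nu - 1) / (nu * sigma),
    log(y / mu) / sigma
  )
}

# mass of the untruncated t transform that lands in y > 0
bct_trunc_norm <- function(sigma, nu, tau) {
  a <- ifelse(abs(nu) > 1e-12, 1 / (sigma * abs(nu)), Inf)
  pt(a, df = tau)
}

#' @rdname bct
#' @export
dbct <- function(x, mu, sigma, nu, tau, log = FALSE) {
  check_bct_params(mu, sigma, tau)
  k <- max(length(x), length(mu), length(sigma), length(nu), length(tau))
  x <- rep_len(x, k); mu <- rep_len(mu, k); sigma <- rep_len(sigma, k)
  nu <- rep_len(nu, k); tau <- rep_len(tau, k)
  if (any(x <= 0)) {
    stop_refcal("BCT density is defined for positive values only.",
                "refcal_domain_error")
  }
  z <- bct_z(x, mu, sigma, nu)
  logf <- (nu - 1) * base::log(x) - nu * base::log(mu) - base::log(sigma) +
    dt(z, df = tau, log = TRUE) - base::log(bct_trunc_norm(sigma, nu, tau))
  if (log) logf else exp(logf)
}

#' @rdname bct
#' @export
pbct <- function(q, mu, sigma, nu, tau, log.p = FALSE) {
  check_bct_params(mu, sigma, tau)
  k <- max(length(q), length(mu), length(sigma), length(nu), length(tau))
  q <- rep_len(q, k); mu <- rep_len(mu, k); sigma <- rep_len(sigma, k)
  nu <- rep_len(nu, k); tau <- rep_len(tau, k)
  if (any(q <= 0)) {
    stop_refcal("BCT CDF is defined for positive values only.",
                "refcal_domain_error")
  }
  z <- bct_z(q, mu, sigma, nu)
  norm <- bct_trunc_norm(sigma, nu, tau)
  lower_mass <- ifelse(nu > 1e-12, pt(-1 / (sigma * nu), df = tau), 0)
  p <- (pt(z, df = tau) - lower_mass) / norm
  p <- pmin(pmax(p, 0), 1)
  if (log.p) base::log(p) else p
}

#' @rdname bct
#' @export
qbct <- function(p, mu, sigma, nu, tau) {
  check_bct_params(mu, sigma, tau)
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    stop_refcal("`p` must lie strictly inside (0, 1).", "refcal_domain_error")
  }
  k <- max(length(p), length(mu), length(sigma), length(nu), length(tau))
  p <- rep_len(p, k); mu <- rep_len(mu, k); sigma <- rep_len(sigma, k)
  nu <- rep_len(nu, k); tau <- rep_len(tau, k)
  norm <- bct_trunc_norm(sigma, nu, tau)
  z <- ifelse(nu > 1e-12,
    qt(1 - (1 - p) * norm, df = tau),
    qt(p * norm, df = tau)
  )
  arg <- ifelse(abs(nu) > 1e-12, nu * sigma * z + 1, NA_real_)
  if (any(abs(nu) > 1e-12 & arg <= 0)) {
    stop_refcal(
      "Requested quantile is unreachable for these parameters (power argument <= 0).",
      "refcal_domain_error"
    )
  }
  ifelse(abs(nu) > 1e-12, mu * arg^(1 / nu), mu * exp(sigma * z))
}

#' @rdname bct
#' @export
rbct <- function(n, mu, sigma, nu, tau) {
  qbct(runif(n), mu = mu, sigma = sigma, nu = nu, tau = tau)
}

#' Box-Cox t log-likelihood
#'
#' Sum of per-observation BCT log-densities, including the truncation
#' normaliser for positivity. Used as the objective of the
#' location-scale-shape fitters.
#'
#' @param values positive observations.
#' @param mu,sigma per-observation location and scale (recycled).
#' @param nu,tau shared skewness power and degrees of freedom.
#' @return scalar log-likelihood.
#' @export
bct_loglik <- function(values, mu, sigma, nu, tau) {
  if (length(values) == 0) {
    stop_refcal("`values` must be nonempty.", "refcal_domain_error")
  }
  sum(dbct(values, mu = mu, sigma = sigma, nu = nu, tau = tau, log = TRUE))
}
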