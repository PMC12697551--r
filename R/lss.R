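#' Fit a Box-Cox t location-scale-shape regression
#'
#' Fits a distributional regression for a positive phenotype in which the BCT
#' location `mu` and log-scale `log(sigma)` are each modelled as a smooth
#' cubic B-spline function of age plus a fixed sex offset, while the skewness
#' power `nu` and tail degrees of freedom `tau` are held constant. The fit
#' maximises the penalized BCT log-likelihood (second-order difference
#' penalty on each spline coefficient block) by quasi-Newton (BFGS)
#' optimisation.
#'
#' Initialisation: `mu` coefficients from a penalized least-squares fit of
#' the values on the basis, `sigma` from the residual coefficient of
#' variation, `nu = 1`, `tau = 10`.
#'
#' @param data data frame with columns `age`, `sex` (levels F/M) and `value`
#'   (> 0). Extra columns are ignored.
#' @param config list of fitting options; see [lss_control()].
#' @return an object of class `lss_fit` with the basis definition,
#'   coefficient vectors for location and log-scale, constant `nu` and `tau`,
#'   the penalized objective at initialisation and at the solution, and a
#'   convergence flag.
#' @seealso [naive_interval()], [predict.lss_fit()]
#' @export
fit_lss <- function(data, config = lss_control()) {
  config <- utils::modifyList(lss_control(), config)
  data <- as_tibble(data)
  n <- nrow(data)
  if (n < config$min_n) {
    stop_fit_error(paste0(
      "Need at least ", config$min_n, " observations to fit (got ", n, ")."
    ))
  }
  if (any(!is.finite(data$value)) || any(data$value <= 0)) {
    stop_refcal("All `value` entries must be finite and > 0.",
                "refcal_domain_error")
  }
  check_sex_levels(data$sex)

  basis <- make_age_basis(data$age, n_knots = config$n_knots)
  X <- lss_design(basis, data$age, data$sex)
  k <- basis_dim(basis)
  p <- ncol(X)
  P <- matrix(0, p, p)
  P[seq_len(k), seq_len(k)] <- diff_penalty(k)
  lambda <- config$lambda
  y <- data$value

  # penalized least-squares initialisation for the location curve
  b_mu0 <- solve(crossprod(X) + lambda * P + 1e-8 * diag(p), crossprod(X, y))
  resid0 <- y - drop(X %*% b_mu0)
  sigma0 <- max(sd(resid0) / mean(y), 1e-4)
  b_s0 <- c(rep(base::log(sigma0), k), 0)
  theta0 <- c(b_mu0, b_s0, 1, base::log(10))

  unpack <- function(theta) {
    list(
      b_mu = theta[seq_len(p)],
      b_s = theta[p + seq_len(p)],
      nu = theta[2 * p + 1],
      log_tau = theta[2 * p + 2]
    )
  }
  objective <- function(theta) {
    par <- unpack(theta)
    mu <- drop(X %*% par$b_mu)
    if (any(mu <= 0)) return(1e10)
    sigma <- exp(pmin(drop(X %*% par$b_s), 20))
    tau <- exp(pmin(par$log_tau, 20))
    ll <- tryCatch(
      bct_loglik(y, mu, sigma, par$nu, tau),
      error = function(e) -Inf
    )
    if (!is.finite(ll)) return(1e10)
    pen <- lambda * (
      drop(crossprod(par$b_mu[seq_len(k)], P[seq_len(k), seq_len(k)] %*%
                       par$b_mu[seq_len(k)])) +
      drop(crossprod(par$b_s[seq_len(k)], P[seq_len(k), seq_len(k)] %*%
                       par$b_s[seq_len(k)]))
    )
    -ll + pen
  }

  init_obj <- objective(theta0)
  opt <- optim(theta0, objective,
    method = "BFGS",
    control = list(maxit = config$max_iter, reltol = config$reltol)
  )
  if (opt$convergence != 0 && opt$value > init_obj) {
    stop_fit_error(
      "Location-scale-shape fit did not converge.",
      objective_trace = c(init = init_obj, final = opt$value)
    )
  }
  par <- unpack(opt$par)
  mu_hat <- drop(X %*% par$b_mu)
  sigma_hat <- exp(drop(X %*% par$b_s))
  tau_hat <- exp(par$log_tau)

  structure(
    list(
      basis = basis,
      coef_mu = par$b_mu,
      coef_sigma = par$b_s,
      nu = par$nu,
      tau = tau_hat,
      lambda = lambda,
      n = n,
      logLik = bct_loglik(y, mu_hat, sigma_hat, par$nu, tau_hat),
      objective = opt$value,
      init_objective = init_obj,
      converged = opt$convergence == 0,
      iterations = opt$counts[["function"]],
      age_range = range(data$age),
      sexes = c("F", "M")
    ),
    class = "lss_fit"
  )
}

#' Control options for the location-scale-shape fitter
#'
#' @param n_knots interior knots for the cubic age spline (placed at age
#'   quantiles); default 10.
#' @param lambda second-order difference penalty weight; default 1.
#' @param min_n minimum sample size; default 50.
#' @param max_iter,reltol BFGS stopping rule.
#' @return a named list of options.
#' @export
lss_control <- function(n_knots = 10, lambda = 1, min_n = 50,
                        max_iter = 200, reltol = 1e-8) {
  list(n_knots = n_knots, lambda = lambda, min_n = min_n,
       max_iter = max_iter, reltol = reltol)
}

#' Predict BCT parameters from a fitted location-scale-shape model
#'
#' @param object an `lss_fit`.
#' @param newdata data frame with `age` and `sex` columns.
#' @param ... unused.
#' @return tibble with one row per input row and columns `mu`, `sigma`,
#'   `nu`, `tau`.
#' @export
predict.lss_fit <- function(object, newdata, ...) {
  check_sex_levels(newdata$sex, object$sexes)
  X <- lss_design(object$basis, newdata$age, newdata$sex)
  tibble(
    mu = drop(X %*% object$coef_mu),
    sigma = exp(drop(X %*% object$coef_sigma)),
    nu = object$nu,
    tau = object$tau
  )
}

#' @export
print.lss_fit <- function(x, ...) {
  cat("Box-Cox t location-scale-shape fit\n")
  cat("  n =", x$n, " nu =", signif(x$nu, 4), " tau =", signif(x$tau, 4), "\n")
  cat("  penalized objective:", signif(x$objective, 8),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  invisible(x)
}

#' Quantile curve of a fitted location-scale-shape model
#'
#' @param object an `lss_fit`.
#' @param p probability in (0, 1).
#' @param newdata data frame with `age` and `sex`.
#' @return numeric vector of conditional quantiles.
#' @export
lss_quantile <- function(object, p, newdata) {
  pars <- predict(object, newdata)
  qbct(p, mu = pars$mu, sigma = pars$sigma, nu = pars$nu, tau = pars$tau)
}
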