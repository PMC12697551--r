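# shared fixtures built in code

# a flat interval [lo, hi] at all covariates
const_interval <- function(alpha = 0.05, lo = 1, hi = 3,
                           age_range = c(18, 100)) {
  new_ref_interval(
    alpha,
    lower = function(age, sex) rep(lo, length(age)),
    upper = function(age, sex) rep(hi, length(age)),
    age_range = age_range
  )
}

# an lss_fit with spatially constant parameters, built directly (B-splines
# sum to one, so equal spline coefficients give a constant curve)
const_lss_fit <- function(mu = 3, sigma = 0.05, nu = 1, tau = 10,
                          age_range = c(20, 95)) {
  basis <- refcal:::make_age_basis(seq(age_range[1], age_range[2],
                                       length.out = 200))
  k <- refcal:::basis_dim(basis)
  structure(
    list(
      basis = basis,
      coef_mu = c(rep(mu, k), 0),
      coef_sigma = c(rep(log(sigma), k), 0),
      nu = nu, tau = tau, lambda = 1, n = 200,
      logLik = NA_real_, objective = NA_real_, init_objective = NA_real_,
      converged = TRUE, iterations = 0L,
      age_range = age_range, sexes = c("F", "M")
    ),
    class = "lss_fit"
  )
}

# records at fixed covariates with given values
records_at <- function(values, age = 50, sex = "F", batch = "b1",
                       group = "CN") {
  tibble::tibble(
    subject_id = sprintf("r%04d", seq_along(values)),
    age = age, sex = sex, batch = batch, value = values, group = group
  )
}

# phenotype-like data from a BCT model with linear age trend in mu
sim_bct_linear <- function(n, intercept = 3.6, slope = -0.008, sigma = 0.06,
                           nu = 1, tau = 10, seed = 1) {
  set.seed(seed)
  age <- runif(n, 20, 95)
  sex <- sample(c("F", "M"), n, replace = TRUE)
  mu <- intercept + slope * age
  tibble::tibble(
    subject_id = sprintf("s%05d", seq_len(n)),
    age = age, sex = sex, batch = "b1",
    value = qbct(runif(n), mu = mu, sigma = sigma, nu = nu, tau = tau),
    group = "CN"
  )
}
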