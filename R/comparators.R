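#' Refit a reference interval in the calibration set
#'
#' The simplest alternative to calibration: discard the pre-fitted interval
#' and fit a new naive interval entirely in the calibration sample. Fitting
#' failures (too few records, non-convergence) surface as classed
#' `refcal_fit_error` conditions so a resampling harness can record them as
#' failed trials rather than crash.
#'
#' @param data calibration records (`age`, `sex`, `value`).
#' @param alpha miscoverage level.
#' @param model `"bct_lss"` or `"additive_qr"`.
#' @param config fitting options for the chosen model
#'   ([lss_control()] / [aqr_control()]).
#' @return a naive `ref_interval` with provenance marked `refit`.
#' @export
refit_interval <- function(data, alpha, model = c("bct_lss", "additive_qr"),
                           config = list()) {
  model <- match.arg(model)
  interval <- if (model == "bct_lss") {
    fit <- fit_lss(data, config = utils::modifyList(lss_control(), config))
    naive_interval(fit, alpha)
  } else {
    cfg <- utils::modifyList(aqr_control(), config)
    lo <- fit_aqr(data, alpha / 2, config = cfg)
    hi <- fit_aqr(data, 1 - alpha / 2, config = cfg)
    naive_interval(lo, upper = hi)
  }
  interval$provenance <- paste0("refit:", interval$provenance)
  interval
}

#' Fit a covariate-preserving location-scale harmonizer
#'
#' Estimates a shared smooth-age + sex mean model across batches together
#' with per-batch location shifts, and batch scales either as one scalar
#' standard-deviation ratio per batch (`scalar_scale`, in the spirit of
#' ComBat with a GAM mean) or as covariate-dependent log-scale offsets
#' around a shared smooth log-scale model (`covariate_scale`, in the spirit
#' of location-scale ComBat variants). Fitted on the pooled data with no
#' empirical-Bayes shrinkage across outcomes (single-outcome setting).
#'
#' @param data pooled records with at least 2 batches.
#' @param variant `"covariate_scale"` (default) or `"scalar_scale"`.
#' @param config list with `min_n` (minimum records per batch, default 20)
#'   and `k` (basis dimension of the age smooth, default 10).
#' @return an object of class `harmonizer`.
#' @export
fit_harmonizer <- function(data, variant = c("covariate_scale", "scalar_scale"),
                           config = list()) {
  variant <- match.arg(variant)
  config <- utils::modifyList(list(min_n = 20, k = 10), config)
  data <- as_tibble(data)
  check_sex_levels(data$sex)
  counts <- table(data$batch)
  if (length(counts) < 2) {
    stop_fit_error("Harmonization requires at least 2 batches.")
  }
  small <- names(counts)[counts < config$min_n]
  if (length(small) > 0) {
    stop_fit_error(paste0("Batch(es) below the minimum of ", config$min_n,
                          " records: ", paste(small, collapse = ", "), "."))
  }
  df <- data.frame(
    value = data$value, age = data$age,
    sex = factor(data$sex, levels = c("F", "M")),
    batch = factor(data$batch)
  )
  batches <- levels(df$batch)

  if (variant == "scalar_scale") {
    fit <- mgcv::gam(value ~ s(age, k = config$k) + sex + batch, data = df)
    resid <- df$value - predict(fit, newdata = df)
    s_b <- vapply(split(resid, df$batch), sd, numeric(1))
    model <- list(fit = fit, s_b = s_b, s_pool = sqrt(mean(s_b^2)))
  } else {
    fit <- mgcv::gam(
      list(value ~ s(age, k = config$k) + sex + batch,
           ~ s(age, k = config$k) + batch),
      data = df, family = mgcv::gaulss()
    )
    model <- list(fit = fit)
  }
  structure(
    list(variant = variant, model = model, batches = batches,
         config = config),
    class = "harmonizer"
  )
}

# per-record batch mean and scale plus pooled (batch-averaged) versions
harmonizer_moments <- function(h, data, batch_as = NULL) {
  df <- data.frame(
    age = data$age,
    sex = factor(data$sex, levels = c("F", "M")),
    batch = factor(batch_as %||% data$batch, levels = h$batches)
  )
  if (h$variant == "scalar_scale") {
    m <- as.numeric(predict(h$model$fit, newdata = df))
    s <- unname(h$model$s_b[as.character(df$batch)])
  } else {
    pred <- predict(h$model$fit, newdata = df)
    m <- unname(pred[, 1])
    # gaulss: second linear predictor carries log standard deviation
    s <- exp(unname(pred[, 2]))
  }
  list(m = m, s = s)
}

harmonizer_pooled <- function(h, data) {
  ms <- lapply(h$batches, function(b) {
    harmonizer_moments(h, data, batch_as = rep(b, nrow(data)))
  })
  as_mat <- function(which) {
    matrix(vapply(ms, `[[`, numeric(nrow(data)), which), nrow = nrow(data))
  }
  m <- rowMeans(as_mat("m"))
  s <- if (h$variant == "scalar_scale") {
    rep(h$model$s_pool, nrow(data))
  } else {
    exp(rowMeans(base::log(as_mat("s"))))
  }
  list(m = m, s = s)
}

#' Harmonize records to a common scale
#'
#' Transforms each record as
#' `y* = m_ref(x) + (y - m_b(x)) * s_ref(x) / s_b(x)`, where `m_b`, `s_b`
#' are the fitted mean and scale for the record's batch and `m_ref`, `s_ref`
#' the reference convention: the batch-averaged (pooled) model by default,
#' or a designated batch. Covariates, labels and record count are unchanged.
#'
#' @param harmonizer a fitted [fit_harmonizer()] object.
#' @param data records to transform; every batch must have been seen at fit
#'   time (out-of-sample batches are rejected).
#' @param target `"pooled"` (default) or the label of a reference batch.
#' @return the input tibble with `value` replaced by the harmonized value
#'   and a `value_raw` column holding the original.
#' @export
apply_harmonizer <- function(harmonizer, data, target = "pooled") {
  data <- as_tibble(data)
  unseen <- setdiff(unique(data$batch), harmonizer$batches)
  if (length(unseen) > 0) {
    stop_refcal(paste0("Batch(es) not seen during fitting: ",
                       paste(unseen, collapse = ", "), "."),
                "refcal_unseen_batch")
  }
  own <- harmonizer_moments(harmonizer, data)
  ref <- if (identical(target, "pooled")) {
    harmonizer_pooled(harmonizer, data)
  } else {
    if (!target %in% harmonizer$batches) {
      stop_refcal(paste0("Reference batch `", target, "` unknown."),
                  "refcal_unseen_batch")
    }
    harmonizer_moments(harmonizer, data, batch_as = rep(target, nrow(data)))
  }
  data |>
    dplyr::mutate(
      value_raw = .data$value,
      value = ref$m + (.data$value - own$m) * ref$s / own$s
    )
}

#' Batch effects of a fitted harmonizer
#'
#' @param x a `harmonizer`.
#' @param at age at which covariate-dependent effects are evaluated
#'   (default: midpoint of the fitted ages).
#' @param ... unused.
#' @return tibble with one row per batch: estimated location `shift` and
#'   `scale` ratio relative to the pooled convention.
#' @export
tidy.harmonizer <- function(x, at = NULL, ...) {
  ages <- x$model$fit$model$age
  at <- at %||% mean(range(ages))
  probe <- tibble(age = at, sex = "F", batch = x$batches[1], value = NA_real_)
  pooled <- harmonizer_pooled(x, probe)
  purrr::map_dfr(x$batches, function(b) {
    mb <- harmonizer_moments(x, probe, batch_as = b)
    tibble(batch = b, shift = mb$m - pooled$m, scale = mb$s / pooled$s)
  })
}

#' Fit a batch-adjusted location-scale-shape model
#'
#' Extends [fit_lss()] with per-batch offsets in the location and in the
#' log-scale, shrunk toward zero by a ridge penalty (a deterministic
#' approximation of normal random effects for batch in both the mean and
#' variance). The interval for a target batch uses that batch's offsets, so
#' a chart fitted on pooled multi-site data can be adjusted to the batch a
#' new observation comes from.
#'
#' @param data pooled records with >= 2 batches (a single batch reduces to
#'   [fit_lss()] up to optimizer tolerance).
#' @param config [lss_control()] options plus `ridge` (offset penalty
#'   weight; default 50, corresponding to a prior SD of about 0.1 phenotype
#'   units).
#' @return an object of class `batch_lss_fit`.
#' @export
fit_batch_lss <- function(data, config = lss_control()) {
  config <- utils::modifyList(c(lss_control(), list(ridge = 50)), config)
  data <- as_tibble(data)
  n <- nrow(data)
  if (n < config$min_n) {
    stop_fit_error(paste0("Need at least ", config$min_n,
                          " observations (got ", n, ")."))
  }
  check_sex_levels(data$sex)
  if (any(data$value <= 0)) {
    stop_refcal("All `value` entries must be > 0.", "refcal_domain_error")
  }
  batches <- sort(unique(data$batch))
  nb <- length(batches)
  B <- outer(data$batch, batches, `==`) * 1 # n x nb indicator

  basis <- make_age_basis(data$age, n_knots = config$n_knots)
  X <- lss_design(basis, data$age, data$sex)
  k <- basis_dim(basis)
  p <- ncol(X)
  Pk <- diff_penalty(k)
  lambda <- config$lambda
  ridge <- config$ridge
  y <- data$value

  Pfull <- matrix(0, p, p)
  Pfull[seq_len(k), seq_len(k)] <- Pk
  b_mu0 <- solve(crossprod(X) + lambda * Pfull + 1e-8 * diag(p),
                 crossprod(X, y))
  sigma0 <- max(sd(y - drop(X %*% b_mu0)) / mean(y), 1e-4)
  theta0 <- c(b_mu0, rep(0, nb), c(rep(base::log(sigma0), k), 0),
              rep(0, nb), 1, base::log(10))

  idx <- list(
    mu = seq_len(p),
    u = p + seq_len(nb),
    s = p + nb + seq_len(p),
    v = 2 * p + nb + seq_len(nb),
    nu = 2 * (p + nb) + 1,
    log_tau = 2 * (p + nb) + 2
  )

  objective <- function(theta) {
    b_mu <- theta[idx$mu]; u <- theta[idx$u]
    b_s <- theta[idx$s]; v <- theta[idx$v]
    nu <- theta[idx$nu]; tau <- exp(pmin(theta[idx$log_tau], 20))
    mu <- drop(X %*% b_mu) + drop(B %*% u)
    if (any(mu <= 0)) return(1e10)
    sigma <- exp(pmin(drop(X %*% b_s) + drop(B %*% v), 20))
    ll <- tryCatch(bct_loglik(y, mu, sigma, nu, tau),
                   error = function(e) -Inf)
    if (!is.finite(ll)) return(1e10)
    pen <- lambda * (drop(crossprod(b_mu[seq_len(k)], Pk %*% b_mu[seq_len(k)])) +
                       drop(crossprod(b_s[seq_len(k)], Pk %*% b_s[seq_len(k)]))) +
      ridge * (sum(u^2) + sum(v^2))
    -ll + pen
  }

  init_obj <- objective(theta0)
  opt <- optim(theta0, objective, method = "BFGS",
               control = list(maxit = config$max_iter, reltol = config$reltol))
  if (opt$convergence != 0 && opt$value > init_obj) {
    stop_fit_error("Batch-adjusted fit did not converge.",
                   objective_trace = c(init = init_obj, final = opt$value))
  }
  structure(
    list(
      basis = basis,
      coef_mu = opt$par[idx$mu], coef_sigma = opt$par[idx$s],
      offsets = tibble(batch = batches,
                       location = opt$par[idx$u],
                       log_scale = opt$par[idx$v]),
      nu = opt$par[idx$nu], tau = exp(opt$par[idx$log_tau]),
      lambda = lambda, ridge = ridge, n = n,
      objective = opt$value, init_objective = init_obj,
      converged = opt$convergence == 0,
      age_range = range(data$age), sexes = c("F", "M")
    ),
    class = "batch_lss_fit"
  )
}

#' Predict BCT parameters for a target batch
#'
#' @param object a `batch_lss_fit`.
#' @param newdata data frame with `age` and `sex`.
#' @param batch single target batch label (must have been in the pooled
#'   fit).
#' @param ... unused.
#' @return tibble with columns `mu`, `sigma`, `nu`, `tau`.
#' @export
predict.batch_lss_fit <- function(object, newdata, batch, ...) {
  row <- object$offsets[object$offsets$batch == batch, ]
  if (nrow(row) != 1) {
    stop_refcal(paste0("Batch `", batch, "` not present in the fit."),
                "refcal_unseen_batch")
  }
  check_sex_levels(newdata$sex, object$sexes)
  X <- lss_design(object$basis, newdata$age, newdata$sex)
  tibble(
    mu = drop(X %*% object$coef_mu) + row$location,
    sigma = exp(drop(X %*% object$coef_sigma) + row$log_scale),
    nu = object$nu, tau = object$tau
  )
}

#' @describeIn fit_batch_lss naive interval for a target batch.
#' @param object a `batch_lss_fit`.
#' @param alpha miscoverage level.
#' @param batch target batch label.
#' @param ... unused.
#' @export
naive_interval.batch_lss_fit <- function(object, alpha, batch, ...) {
  fit <- object
  qfun <- function(p) {
    function(age, sex) {
      pars <- predict(fit, tibble(age = age, sex = sex), batch = batch)
      qbct(p, pars$mu, pars$sigma, pars$nu, pars$tau)
    }
  }
  new_ref_interval(
    alpha, lower = qfun(alpha / 2), upper = qfun(1 - alpha / 2),
    provenance = sprintf("batch_lss(n=%d, batch=%s)", fit$n, batch),
    age_range = fit$age_range, sexes = fit$sexes
  )
}
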