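#' Simulation parameters for multi-site phenotype data
#'
#' Describes a generating distribution for one-row-per-scan phenotype
#' records: a smooth mean trajectory over age with a sex offset, an
#' age-dependent scale, a noise family, per-batch location shifts and scale
#' multipliers, and a disease subgroup with reduced values. Defaults are
#' chosen to resemble cortical-thickness-like measurements (millimetre
#' magnitudes, adult age range): mean
#' `3.8 - 0.012 age + 4e-5 age^2 + 0.05 [sex = M]`, scale
#' `0.12 + 0.0006 age`, age uniform on 20-95.
#'
#' @param mean_coef coefficients `(intercept, age, age^2, sexM)` of the mean
#'   curve.
#' @param scale_coef coefficients `(intercept, age)` of the noise scale
#'   curve; must stay positive over `age_range`.
#' @param age_range sampling range of ages (uniform).
#' @param case_age_range sampling range of ages for the disease subgroup
#'   (shifted older by default).
#' @param prop_male probability a record is male.
#' @param noise one of `noise_gaussian()`, `noise_student_t()`,
#'   `noise_bct()`.
#' @param batches tibble with columns `batch` (label), `shift` (additive
#'   location shift) and `scale` (multiplier on the noise scale, > 0).
#' @param disease_effect mean reduction for `group = "CASE"` records.
#' @return an object of class `sim_params`.
#' @export
sim_params <- function(mean_coef = c(3.8, -0.012, 4e-5, 0.05),
                       scale_coef = c(0.12, 0.0006),
                       age_range = c(20, 95),
                       case_age_range = c(55, 95),
                       prop_male = 0.45,
                       noise = noise_gaussian(),
                       batches = tibble(batch = "batch1", shift = 0, scale = 1),
                       disease_effect = 0.3) {
  batches <- as_tibble(batches)
  stopifnot(all(c("batch", "shift", "scale") %in% names(batches)))
  if (any(batches$scale <= 0)) {
    stop_refcal("Batch scale multipliers must be > 0.", "refcal_config_error")
  }
  sc <- scale_coef[1] + scale_coef[2] * seq(age_range[1], age_range[2],
                                            length.out = 50)
  if (any(sc <= 0)) {
    stop_refcal("Scale curve must be positive over the age range.",
                "refcal_config_error")
  }
  structure(
    list(mean_coef = mean_coef, scale_coef = scale_coef,
         age_range = age_range, case_age_range = case_age_range,
         prop_male = prop_male, noise = noise, batches = batches,
         disease_effect = disease_effect),
    class = "sim_params"
  )
}

#' Noise families for the synthetic generator
#'
#' `noise_gaussian()` draws standard normal errors; `noise_student_t()`
#' draws (unstandardised) t errors with `df` degrees of freedom for heavier
#' tails; `noise_bct()` draws skewed heavy-tailed errors as
#' `(B - 1) / 0.2` where `B` follows a BCT distribution with `mu = 1`,
#' `sigma = 0.2` and the given shape parameters, giving roughly unit-scale,
#' zero-centred noise with controllable skew and tail weight.
#'
#' @param df degrees of freedom (> 0).
#' @param nu,tau BCT skewness power and tail degrees of freedom.
#' @return a noise-family object used by [simulate_study()].
#' @name noise_families
NULL

#' @rdname noise_families
#' @export
noise_gaussian <- function() {
  structure(list(family = "gaussian", draw = function(n) rnorm(n)),
            class = "refcal_noise")
}

#' @rdname noise_families
#' @export
noise_student_t <- function(df = 5) {
  stopifnot(df > 0)
  structure(list(family = "student_t", df = df,
                 draw = function(n) rt(n, df = df)),
            class = "refcal_noise")
}

#' @rdname noise_families
#' @export
noise_bct <- function(nu = 0.5, tau = 8) {
  structure(list(family = "bct", nu = nu, tau = tau,
                 draw = function(n) (rbct(n, 1, 0.2, nu, tau) - 1) / 0.2),
            class = "refcal_noise")
}

sim_mean <- function(params, age, sex) {
  params$mean_coef[1] + params$mean_coef[2] * age +
    params$mean_coef[3] * age^2 + params$mean_coef[4] * (sex == "M")
}

sim_scale <- function(params, age) {
  params$scale_coef[1] + params$scale_coef[2] * age
}

#' Derive a reproducible sub-seed from a master seed
#'
#' Deterministic integer recurrence used to give each trial (or other
#' counted unit) its own independent, individually reproducible RNG stream.
#' The result always lies in `[1, 2^31 - 2]`.
#'
#' @param master integer master seed.
#' @param counter non-negative integer stream index.
#' @return an integer seed.
#' @export
derive_seed <- function(master, counter) {
  m <- 2147483629
  s <- (as.numeric(master) %% m)
  s <- (s * 48271 + as.numeric(counter) * 16807 + 11) %% m
  as.integer(s + 1)
}

#' Simulate a multi-site phenotype study
#'
#' Generates records with
#' `value = mu(age, sex) + shift_b - disease_effect * [CASE] +
#' scale_b * sigma(age) * eps`, where `eps` is drawn from the configured
#' noise family. Reproducible given `seed`.
#'
#' @param params a [sim_params()] object.
#' @param n controls per batch (recycled over batches).
#' @param n_case disease-group records per batch (recycled; default 0).
#' @param seed integer seed.
#' @return tibble of phenotype records (`subject_id`, `age`, `sex`, `batch`,
#'   `value`, `group`).
#' @export
simulate_study <- function(params, n, n_case = 0, seed = 1) {
  stopifnot(inherits(params, "sim_params"))
  if (!inherits(params$noise, "refcal_noise")) {
    stop_refcal("`params$noise` must be a noise-family object.",
                "refcal_config_error")
  }
  nb <- nrow(params$batches)
  n <- rep_len(n, nb)
  n_case <- rep_len(n_case, nb)
  if (any(n < 1)) {
    stop_refcal("`n` must be >= 1 per batch.", "refcal_config_error")
  }
  set.seed(seed)
  rows <- vector("list", nb)
  counter <- 0L
  for (b in seq_len(nb)) {
    nn <- n[b] + n_case[b]
    group <- c(rep("CN", n[b]), rep("CASE", n_case[b]))
    age <- numeric(nn)
    cn <- group == "CN"
    age[cn] <- runif(sum(cn), params$age_range[1], params$age_range[2])
    age[!cn] <- runif(sum(!cn), params$case_age_range[1],
                      params$case_age_range[2])
    sex <- ifelse(runif(nn) < params$prop_male, "M", "F")
    eps <- params$noise$draw(nn)
    value <- sim_mean(params, age, sex) + params$batches$shift[b] -
      params$disease_effect * (group == "CASE") +
      params$batches$scale[b] * sim_scale(params, age) * eps
    rows[[b]] <- tibble(
      subject_id = sprintf("S%s_%06d", params$batches$batch[b],
                           counter + seq_len(nn)),
      age = age, sex = sex, batch = params$batches$batch[b],
      value = value, group = group
    )
    counter <- counter + nn
  }
  dplyr::bind_rows(rows)
}

#' Split records into reference, calibration and validation sets
#'
#' Samples the reference set (without replacement) from the cognitively
#' normal records of the reference batches, the calibration set from the CN
#' records of the test batch, and assigns every remaining CN test-batch
#' record to the validation set. The three sets are disjoint by
#' construction and the calibration size is recorded.
#'
#' @param data phenotype records.
#' @param n_ref,n_cal requested reference and calibration sizes.
#' @param ref_batches character vector of reference batch labels.
#' @param test_batch single test batch label (disjoint from
#'   `ref_batches`).
#' @param seed integer seed.
#' @return an object of class `data_split`: list with `reference_ids`,
#'   `calibration_ids`, `validation_ids` and `n_cal`.
#' @export
make_splits <- function(data, n_ref, n_cal, ref_batches, test_batch, seed = 1) {
  data <- as_tibble(data)
  if (test_batch %in% ref_batches) {
    stop_refcal("`test_batch` must be disjoint from `ref_batches`.",
                "refcal_config_error")
  }
  ref_pool <- data$subject_id[data$batch %in% ref_batches & data$group == "CN"]
  test_pool <- data$subject_id[data$batch == test_batch & data$group == "CN"]
  if (n_ref > length(ref_pool)) {
    stop_refcal(paste0("Requested n_ref = ", n_ref, " but only ",
                       length(ref_pool), " CN reference records available."),
                "refcal_config_error")
  }
  if (n_cal >= length(test_pool)) {
    stop_refcal(paste0("Requested n_cal = ", n_cal, " but only ",
                       length(test_pool), " CN test records available ",
                       "(validation set would be empty)."),
                "refcal_config_error")
  }
  set.seed(seed)
  reference_ids <- sample(ref_pool, n_ref)
  calibration_ids <- sample(test_pool, n_cal)
  validation_ids <- setdiff(test_pool, calibration_ids)
  structure(
    list(reference_ids = reference_ids, calibration_ids = calibration_ids,
         validation_ids = validation_ids, n_cal = length(calibration_ids)),
    class = "data_split"
  )
}

#' Named scenario presets for the resampling experiments
#'
#' Returns a pair of generating configurations (reference population P, test
#' population Q) emulating three study designs: `exp1_large_shift` — the
#' reference population differs from the test population by a large location
#' shift (+0.3) and scale inflation (x1.5), as when charts fitted on one
#' study/scanner are applied to a very different acquisition;
#' `exp2_small_shift` — a small shift (+0.08, x1.1), as between field
#' strengths within one study; `exp3_multisite` — 22 reference batches with
#' heterogeneous shifts and scales plus one test batch and a disease
#' subgroup.
#'
#' @param name one of `"exp1_large_shift"`, `"exp2_small_shift"`,
#'   `"exp3_multisite"`.
#' @return list with elements `reference` and `test`, both [sim_params()].
#' @export
scenario_presets <- function(name) {
  presets <- c("exp1_large_shift", "exp2_small_shift", "exp3_multisite")
  if (!name %in% presets) {
    stop_refcal(paste0("Unknown preset `", name, "`. Available: ",
                       paste(presets, collapse = ", "), "."),
                "refcal_config_error")
  }
  test <- sim_params(
    batches = tibble(batch = "test", shift = 0, scale = 1)
  )
  if (name == "exp1_large_shift") {
    reference <- sim_params(
      batches = tibble(batch = "ref", shift = 0.3, scale = 1.5),
      disease_effect = 0
    )
  } else if (name == "exp2_small_shift") {
    reference <- sim_params(
      batches = tibble(batch = "ref", shift = 0.08, scale = 1.1),
      disease_effect = 0
    )
  } else {
    # deterministic heterogeneous site effects: normal scores, no RNG
    z <- stats::qnorm((seq_len(22) - 0.5) / 22)
    reference <- sim_params(
      batches = tibble(
        batch = sprintf("site%02d", 1:22),
        shift = z * 0.1,
        scale = exp(rev(z) * 0.15)
      ),
      disease_effect = 0
    )
  }
  list(reference = reference, test = test)
}
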