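#' False positive rate of an interval on a validation set
#'
#' Fractions of (healthy) validation records classified below, above, or
#' anywhere outside the interval by [evaluate_membership()].
#'
#' @param interval a `ref_interval`.
#' @param data nonempty validation records.
#' @return one-row tibble with `fpr_total`, `fpr_lower`, `fpr_upper`.
#' @export
false_positive_rate <- function(interval, data) {
  data <- as_tibble(data)
  if (nrow(data) == 0) {
    stop_refcal("Validation set is empty.", "refcal_empty_set")
  }
  m <- evaluate_membership(interval, data)$membership
  tibble(
    fpr_total = mean(m != "inside"),
    fpr_lower = mean(m == "below"),
    fpr_upper = mean(m == "above")
  )
}

#' Positive rate of an interval on a disease group
#'
#' @param interval a `ref_interval`.
#' @param data nonempty disease-group records.
#' @return fraction of records falling outside the interval.
#' @export
positive_rate <- function(interval, data) {
  data <- as_tibble(data)
  if (nrow(data) == 0) {
    stop_refcal("Case set is empty.", "refcal_empty_set")
  }
  mean(evaluate_membership(interval, data)$membership != "inside")
}

#' Configuration of a resampling experiment
#'
#' @param scenario preset name (see [scenario_presets()]) or a list with
#'   elements `reference` and `test`, both [sim_params()].
#' @param ref_sizes reference-set sizes to sweep.
#' @param cal_sizes calibration-set sizes to sweep.
#' @param alphas interval miscoverage levels.
#' @param n_trials number of resampled trials per combination.
#' @param methods subset of `"unadjusted"`, `"reform"`, `"refit"`,
#'   `"combat_gam"`, `"combat_ls"`, `"batch_lss"`.
#' @param model naive interval model, `"bct_lss"` or `"additive_qr"`.
#' @param n_ref_pool,n_test_pool CN records generated per trial for the
#'   reference population (per batch) and the test batch.
#' @param n_case disease-group records generated in the test batch.
#' @param tail_level,overflow conformal options (see [reform_calibrate()]).
#' @param refit_config overrides of the fitting options used by the refit
#'   arm: by default a lower minimum n, an adaptive knot count and a heavier
#'   smoothing penalty, so small calibration sets can be refit at all
#'   without gross overfitting of the tail curves.
#' @param seed master seed; each trial derives its own stream via
#'   [derive_seed()].
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(scenario = "exp1_large_shift",
                              ref_sizes = c(50, 200, 1000),
                              cal_sizes = c(20, 40, 80, 120, 160, 200,
                                            300, 400, 500, 600),
                              alphas = c(0.1, 0.05, 0.01),
                              n_trials = 1000,
                              methods = c("unadjusted", "reform", "refit"),
                              model = c("bct_lss", "additive_qr"),
                              n_ref_pool = 1200,
                              n_test_pool = 1600,
                              n_case = 0,
                              tail_level = "half_alpha",
                              overflow = "max",
                              refit_config = list(min_n = 20, lambda = 100),
                              seed = 1) {
  model <- match.arg(model)
  known <- c("unadjusted", "reform", "refit", "combat_gam", "combat_ls",
             "batch_lss")
  bad <- setdiff(methods, known)
  if (length(bad) > 0) {
    stop_refcal(paste0("Unknown method(s): ", paste(bad, collapse = ", "),
                       ". Available: ", paste(known, collapse = ", "), "."),
                "refcal_config_error")
  }
  if (n_trials < 1 || any(alphas <= 0) || any(alphas >= 1)) {
    stop_refcal("Need n_trials >= 1 and alphas in (0, 1).",
                "refcal_config_error")
  }
  params <- if (is.character(scenario)) scenario_presets(scenario) else scenario
  stopifnot(inherits(params$reference, "sim_params"),
            inherits(params$test, "sim_params"))
  n_ref_avail <- n_ref_pool * nrow(params$reference$batches)
  if (max(ref_sizes) > n_ref_avail || max(cal_sizes) >= n_test_pool) {
    stop_refcal(
      paste0("Infeasible sizes: reference pool ", n_ref_avail,
             ", test pool ", n_test_pool, "."),
      "refcal_config_error"
    )
  }
  structure(
    list(scenario = params, ref_sizes = ref_sizes, cal_sizes = cal_sizes,
         alphas = alphas, n_trials = n_trials, methods = methods,
         model = model, n_ref_pool = n_ref_pool, n_test_pool = n_test_pool,
         n_case = n_case, tail_level = tail_level, overflow = overflow,
         refit_config = refit_config, seed = seed),
    class = "experiment_config"
  )
}

fit_naive_on <- function(data, alpha, model, config = list()) {
  if (model == "bct_lss") {
    naive_interval(fit_lss(data, config = utils::modifyList(lss_control(),
                                                            config)), alpha)
  } else {
    cfg <- utils::modifyList(aqr_control(), config)
    lo <- fit_aqr(data, alpha / 2, config = cfg)
    hi <- suppressWarnings(fit_aqr(data, 1 - alpha / 2, config = cfg))
    suppressWarnings(naive_interval(lo, upper = hi))
  }
}

adaptive_knots <- function(n) min(10L, max(2L, floor(n / 40)))

#' Run a resampled evaluation of interval-calibration methods
#'
#' For each trial: simulate a reference population and a test population
#' from the configured scenario, split the test batch into calibration and
#' validation sets, fit the naive interval on the drawn reference set, run
#' every configured method, and score the false positive rate (and the
#' positive rate when disease-group records are generated) on the shared
#' validation set. Fit failures in any method are recorded as
#' `status = "fit_error"` rows and never abort the sweep. The result is
#' fully reproducible from the master seed and row order is deterministic.
#'
#' @param config an [experiment_config()].
#' @param progress print a line per trial block.
#' @return tibble with one row per (trial, ref_size, cal_size, alpha,
#'   method): FPR components, `pr` (NA when no cases), and `status`.
#' @export
run_experiment <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  ref_params <- config$scenario$reference
  test_params <- config$scenario$test
  ref_batches <- ref_params$batches$batch
  test_batch <- test_params$batches$batch[1]
  multi_ref <- length(ref_batches) > 1

  rows <- list()
  for (trial in seq_len(config$n_trials)) {
    tseed <- derive_seed(config$seed, trial)
    ref_data <- simulate_study(ref_params, n = config$n_ref_pool,
                               seed = tseed)
    test_data <- simulate_study(test_params, n = config$n_test_pool,
                                n_case = config$n_case,
                                seed = derive_seed(tseed, 1))
    pooled <- dplyr::bind_rows(ref_data, test_data)
    case_data <- dplyr::filter(test_data, .data$group == "CASE")

    for (ref_size in config$ref_sizes) {
      for (cal_size in config$cal_sizes) {
        split <- make_splits(pooled, ref_size, cal_size,
                             ref_batches, test_batch,
                             seed = derive_seed(tseed, 7 + cal_size))
        ref_set <- pooled[pooled$subject_id %in% split$reference_ids, ]
        cal_set <- pooled[pooled$subject_id %in% split$calibration_ids, ]
        val_set <- pooled[pooled$subject_id %in% split$validation_ids, ]

        for (alpha in config$alphas) {
          naive <- tryCatch(
            fit_naive_on(ref_set, alpha, config$model),
            refcal_fit_error = function(e) e
          )
          for (method in config$methods) {
            row <- tibble(
              trial = trial, method = method, model = config$model,
              ref_size = ref_size, cal_size = cal_size, alpha = alpha,
              fpr_total = NA_real_, fpr_lower = NA_real_,
              fpr_upper = NA_real_, pr = NA_real_, status = "ok"
            )
            # each method yields an (interval, validation data, case data)
            # triple: harmonization methods keep the naive interval and
            # transform the data onto the reference scale instead
            scored <- tryCatch({
              if (method %in% c("unadjusted", "reform", "combat_gam",
                                "combat_ls") &&
                  inherits(naive, "condition")) {
                rlang::cnd_signal(naive)
              }
              if (method %in% c("combat_gam", "combat_ls")) {
                variant <- if (method == "combat_gam") "scalar_scale"
                           else "covariate_scale"
                h <- fit_harmonizer(
                  dplyr::bind_rows(ref_set, cal_set), variant = variant
                )
                list(
                  interval = naive,
                  val = apply_harmonizer(h, val_set, target = ref_batches[1]),
                  case = if (nrow(case_data) > 0) {
                    apply_harmonizer(h, case_data, target = ref_batches[1])
                  } else case_data
                )
              } else {
                interval <- switch(method,
                  unadjusted = naive,
                  reform = suppressWarnings(reform_calibrate(
                    naive, cal_set,
                    tail_level = config$tail_level,
                    overflow = config$overflow
                  )),
                  refit = suppressWarnings(refit_interval(
                    cal_set, alpha, model = config$model,
                    config = utils::modifyList(
                      list(n_knots = adaptive_knots(cal_size)),
                      config$refit_config
                    )
                  )),
                  batch_lss = {
                    if (!multi_ref) {
                      stop_fit_error(
                        "batch_lss needs a multi-batch reference dataset."
                      )
                    }
                    bf <- fit_batch_lss(dplyr::bind_rows(ref_set, cal_set))
                    naive_interval(bf, alpha, batch = test_batch)
                  }
                )
                list(interval = interval, val = val_set, case = case_data)
              }
            }, refcal_fit_error = function(e) e)
            if (inherits(scored, "condition")) {
              row$status <- "fit_error"
            } else {
              row[, c("fpr_total", "fpr_lower", "fpr_upper")] <-
                false_positive_rate(scored$interval, scored$val)
              if (nrow(scored$case) > 0) {
                row$pr <- positive_rate(scored$interval, scored$case)
              }
            }
            rows[[length(rows) + 1]] <- row
          }
        }
      }
    }
    if (progress && trial %% 25 == 0) {
      rlang::inform(paste0("trial ", trial, "/", config$n_trials))
    }
  }
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, .data$trial, .data$ref_size, .data$cal_size,
                 .data$alpha, .data$method)
}

#' Summarise resampling trials
#'
#' Median and interquartile range of the FPR (and PR when present) per
#' group, with fit-error trials excluded and counted.
#'
#' @param trials output of [run_experiment()].
#' @param ... grouping columns (defaults to `method`, `ref_size`,
#'   `cal_size`, `alpha`).
#' @return a tibble with medians, quartiles, `n_ok` and `n_error` per
#'   group; groups whose trials all failed keep their row with `n_ok = 0`
#'   and `NA` statistics.
#' @export
summarize_trials <- function(trials, ...) {
  groups <- rlang::enquos(...)
  if (length(groups) == 0) {
    groups <- rlang::quos(.data$method, .data$ref_size, .data$cal_size,
                          .data$alpha)
  }
  missing_cols <- setdiff(c("fpr_total", "status"), names(trials))
  if (length(missing_cols) > 0) {
    stop_refcal(paste0("Trial table lacks column(s): ",
                       paste(missing_cols, collapse = ", "), "."),
                "refcal_schema_error")
  }
  trials |>
    dplyr::group_by(!!!groups) |>
    dplyr::summarise(
      n_ok = sum(.data$status == "ok"),
      n_error = sum(.data$status != "ok"),
      fpr_median = if (any(.data$status == "ok"))
        median(.data$fpr_total[.data$status == "ok"]) else NA_real_,
      fpr_q25 = if (any(.data$status == "ok"))
        unname(quantile(.data$fpr_total[.data$status == "ok"], 0.25)) else NA_real_,
      fpr_q75 = if (any(.data$status == "ok"))
        unname(quantile(.data$fpr_total[.data$status == "ok"], 0.75)) else NA_real_,
      pr_median = if (any(.data$status == "ok" & !is.na(.data$pr)))
        median(.data$pr[.data$status == "ok"], na.rm = TRUE) else NA_real_,
      pr_q25 = if (any(.data$status == "ok" & !is.na(.data$pr)))
        unname(quantile(.data$pr[.data$status == "ok"], 0.25, na.rm = TRUE))
        else NA_real_,
      pr_q75 = if (any(.data$status == "ok" & !is.na(.data$pr)))
        unname(quantile(.data$pr[.data$status == "ok"], 0.75, na.rm = TRUE))
        else NA_real_,
      .groups = "drop"
    )
}

#' One-sample Wilcoxon signed-rank test against a target rate
#'
#' Two-sided (by default) signed-rank test of whether per-trial FPRs are
#' centred on the target level. Zero differences are dropped; for 25 or
#' fewer nonzero differences the exact null distribution of the signed-rank
#' sum is enumerated (midranks, so tied magnitudes are handled), otherwise
#' the normal approximation with continuity correction is used. If every
#' difference is zero the result is degenerate (`p = 1`, flagged).
#'
#' @param x per-trial rates.
#' @param target the nominal level.
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @param sig_level significance threshold for the `significant` flag.
#' @return one-row tibble: `statistic`, `p_value`, `significant`,
#'   `n_nonzero`, `degenerate`.
#' @export
wilcoxon_vs_target <- function(x, target, alternative = "two.sided",
                               sig_level = 0.05) {
  alternative <- match.arg(alternative, c("two.sided", "greater", "less"))
  d <- x - target
  d <- d[is.finite(d)]
  nz <- d[d != 0]
  if (length(nz) == 0) {
    return(tibble(statistic = NA_real_, p_value = 1, significant = FALSE,
                  n_nonzero = 0L, degenerate = TRUE))
  }
  n <- length(nz)
  r <- rank(abs(nz)) # midranks under ties
  w_plus <- sum(r[nz > 0])
  if (n <= 25) {
    # exact null: enumerate sign assignments by convolution over 2 * midranks
    # (integers), which handles tied absolute differences as well
    m <- as.integer(round(2 * r))
    dp <- c(1, rep(0, sum(m)))
    for (mi in m) {
      shifted <- c(rep(0, mi), head(dp, length(dp) - mi))
      dp <- dp + shifted
    }
    dp <- dp / 2^n
    w2 <- as.integer(round(2 * w_plus))
    p_ge <- sum(dp[(w2 + 1):length(dp)])
    p_le <- sum(dp[1:(w2 + 1)])
    p <- switch(alternative,
      greater = p_ge, less = p_le,
      two.sided = min(1, 2 * min(p_ge, p_le))
    )
  } else {
    wt <- suppressWarnings(wilcox.test(nz, mu = 0, alternative = alternative,
                                       exact = FALSE, correct = TRUE))
    p <- wt$p.value
  }
  tibble(statistic = w_plus, p_value = p,
         significant = p < sig_level,
         n_nonzero = n, degenerate = FALSE)
}

#' Paired Wilcoxon signed-rank test between two methods
#'
#' Signed-rank test on the per-trial differences `a - b` for two methods
#' applied to the same data splits.
#'
#' @param a,b equal-length vectors of per-trial rates, paired by trial.
#' @param alternative `"two.sided"`, `"greater"` (a tends to exceed b) or
#'   `"less"`.
#' @param sig_level significance threshold for the flag.
#' @return one-row tibble as in [wilcoxon_vs_target()].
#' @export
wilcoxon_paired <- function(a, b, alternative = "two.sided",
                            sig_level = 0.05) {
  if (length(a) != length(b)) {
    stop_refcal("`a` and `b` must be paired (equal length).",
                "refcal_domain_error")
  }
  wilcoxon_vs_target(a - b, 0, alternative = alternative,
                     sig_level = sig_level)
}

#' Filter trials to a window around the target FPR
#'
#' Retains only those trials in which every compared method achieved an FPR
#' within `alpha * (1 - tol)` to `alpha * (1 + tol)`, so positive rates can
#' be compared among trials where FPR is actually controlled.
#'
#' @param trials output of [run_experiment()].
#' @param alpha target level; only rows at this `alpha` are considered.
#' @param tol tolerance fraction (default 0.2, i.e. the window
#'   `alpha +/- 0.2 alpha`).
#' @return filtered trial table.
#' @export
fpr_window_filter <- function(trials, alpha, tol = 0.2) {
  if (!is.numeric(tol) || tol <= 0) {
    stop_refcal("`tol` must be > 0.", "refcal_domain_error")
  }
  lo <- alpha * (1 - tol)
  hi <- alpha * (1 + tol)
  trials |>
    dplyr::filter(.data$alpha == !!alpha, .data$status == "ok") |>
    dplyr::group_by(.data$trial, .data$ref_size, .data$cal_size) |>
    dplyr::filter(all(.data$fpr_total >= lo & .data$fpr_total <= hi)) |>
    dplyr::ungroup()
}
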