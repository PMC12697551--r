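test_that("false positive rate counts tails as classified", {
  iv <- const_interval(0.05, 1, 3)
  fpr <- false_positive_rate(iv, records_at(c(0.5, 2, 3.5)))
  expect_equal(fpr$fpr_total, 2 / 3)
  expect_equal(fpr$fpr_lower, 1 / 3)
  expect_equal(fpr$fpr_upper, 1 / 3)

  expect_equal(false_positive_rate(iv, records_at(c(1.5, 2, 2.5)))$fpr_total, 0)
  inf_iv <- const_interval(0.05, -Inf, Inf)
  expect_equal(false_positive_rate(inf_iv, records_at(rnorm(50)))$fpr_total, 0)
  expect_error(false_positive_rate(iv, records_at(numeric(0))),
               class = "refcal_empty_set")
})

test_that("positive rate is the outside fraction of the case group", {
  iv <- const_interval(0.05, 1, 3)
  expect_equal(positive_rate(iv, records_at(c(0.1, 0.5), group = "CASE")), 1)
  expect_error(positive_rate(iv, records_at(numeric(0))),
               class = "refcal_empty_set")

  # null case group: PR should sit near alpha under a valid interval
  set.seed(31)
  alpha <- 0.05
  ivn <- const_interval(alpha, qnorm(alpha / 2), qnorm(1 - alpha / 2))
  expect_equal(positive_rate(ivn, records_at(rnorm(5000), group = "CASE")),
               alpha, tolerance = 0.3)
  # a 3-SD downward shift pushes most cases out of a 95% interval
  expect_gt(positive_rate(ivn, records_at(rnorm(500, -3, 1), group = "CASE")),
            0.5)
})

test_that("the resampling harness keeps its bookkeeping promises", {
  cfg <- experiment_config(
    scenario = "exp1_large_shift", ref_sizes = 200, cal_sizes = 40,
    alphas = 0.05, n_trials = 2, methods = c("unadjusted", "reform"),
    n_ref_pool = 300, n_test_pool = 300, seed = 11
  )
  trials <- run_experiment(cfg)
  expect_equal(nrow(trials), 4) # 2 trials x 2 methods
  expect_setequal(unique(trials$method), c("unadjusted", "reform"))
  expect_true(all(trials$status %in% c("ok", "fit_error")))

  trials2 <- run_experiment(cfg)
  expect_identical(trials, trials2)
})

test_that("fit failures are recorded as rows, never crashes", {
  # calibration sets of 15 are below the refit minimum of 20
  cfg <- experiment_config(
    scenario = "exp2_small_shift", ref_sizes = 100, cal_sizes = 15,
    alphas = 0.1, n_trials = 1, methods = c("refit", "reform"),
    n_ref_pool = 200, n_test_pool = 200, seed = 3
  )
  trials <- run_experiment(cfg)
  expect_equal(trials$status[trials$method == "refit"], "fit_error")
  expect_true(is.na(trials$fpr_total[trials$method == "refit"]))
  expect_equal(trials$status[trials$method == "reform"], "ok")
})

test_that("the harness exercises harmonization and batch-adjustment arms", {
  cfg <- experiment_config(
    scenario = "exp2_small_shift", ref_sizes = 300, cal_sizes = 100,
    alphas = 0.1, n_trials = 1,
    methods = c("unadjusted", "reform", "combat_ls", "combat_gam"),
    n_ref_pool = 400, n_test_pool = 400, seed = 5
  )
  trials <- run_experiment(cfg)
  expect_equal(nrow(trials), 4)
  expect_true(all(trials$status == "ok"))
  expect_true(all(trials$fpr_total >= 0 & trials$fpr_total <= 1))
  expect_true(all(trials$fpr_lower + trials$fpr_upper >=
                    trials$fpr_total - 1e-12))
})

test_that("summaries report medians, quartiles and error counts per group", {
  trials <- tibble::tibble(
    trial = c(1, 2, 3, 1, 2, 3), method = rep(c("a", "b"), each = 3),
    ref_size = 100, cal_size = 40, alpha = 0.05,
    fpr_total = c(0.1, 0.2, 0.3, 0.5, NA, NA), pr = NA_real_,
    status = c("ok", "ok", "ok", "ok", "fit_error", "fit_error")
  )
  s <- summarize_trials(trials)
  sa <- s[s$method == "a", ]
  expect_equal(sa$fpr_median, 0.2)
  expect_equal(sa$n_ok, 3)
  sb <- s[s$method == "b", ]
  expect_equal(sb$n_error, 2)

  all_bad <- dplyr::mutate(trials, status = "fit_error", fpr_total = NA_real_)
  sbad <- summarize_trials(all_bad)
  expect_true(all(sbad$n_ok == 0))
  expect_true(all(is.na(sbad$fpr_median)))

  single <- trials[1, ]
  ssing <- summarize_trials(single)
  expect_equal(ssing$fpr_median, 0.1)
  expect_equal(ssing$fpr_q75 - ssing$fpr_q25, 0)

  expect_error(summarize_trials(dplyr::select(trials, -"status")),
               class = "refcal_schema_error")
})

test_that("one-sample signed-rank test reproduces exact small-sample values", {
  # 5 positive differences, no ties: two-sided p = 2/2^5
  res <- wilcoxon_vs_target(0.05 + c(0.01, 0.02, 0.03, 0.04, 0.05), 0.05)
  expect_equal(res$p_value, 0.0625)
  expect_false(res$significant)

  # symmetric values around the target
  sym <- wilcoxon_vs_target(c(0.04, 0.06), 0.05)
  expect_equal(sym$p_value, 1)

  # degenerate: everything exactly on target
  deg <- wilcoxon_vs_target(rep(0.05, 10), 0.05)
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 1)
})

test_that("the signed-rank test holds its level on null samples", {
  set.seed(41)
  reject <- vapply(1:200, function(i) {
    wilcoxon_vs_target(0.05 + rnorm(30, 0, 0.01), 0.05)$significant
  }, logical(1))
  expect_lte(mean(reject), 0.10) # nominal 0.05 plus Monte-Carlo slack
})

test_that("paired signed-rank test matches exact enumeration and flips sides", {
  b <- seq(0.04, 0.06, length.out = 10)
  a <- b + 0.01
  one <- wilcoxon_paired(a, b, alternative = "greater")
  expect_equal(one$p_value, 1 / 1024)
  expect_true(one$significant)

  flipped <- wilcoxon_paired(b, a, alternative = "less")
  expect_equal(flipped$p_value, one$p_value)

  same <- wilcoxon_paired(a, a)
  expect_true(same$degenerate)
  expect_error(wilcoxon_paired(a, b[-1]), class = "refcal_domain_error")
})

test_that("the FPR window filter keeps only jointly controlled trials", {
  trials <- tibble::tibble(
    trial = c(1, 1, 2, 2, 3, 3),
    method = rep(c("reform", "refit"), 3),
    ref_size = 100, cal_size = 40, alpha = 0.05,
    fpr_total = c(0.05, 0.055, 0.05, 0.10, 0.041, 0.059),
    pr = NA_real_, status = "ok"
  )
  kept <- fpr_window_filter(trials, alpha = 0.05, tol = 0.2)
  expect_setequal(unique(kept$trial), c(1, 3)) # trial 2's refit is at 0.10
  expect_equal(nrow(fpr_window_filter(trials, 0.05, tol = 1e6)), 6)
  expect_error(fpr_window_filter(trials, 0.05, tol = -1),
               class = "refcal_domain_error")
})
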