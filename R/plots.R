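#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a reference interval over the phenotype chart
#'
#' @param object a `ref_interval`.
#' @param data optional records to overlay as points, coloured by
#'   membership.
#' @param ... unused.
#' @return a ggplot object (age on x, bounds as lines, one facet per sex).
#' @export
autoplot.ref_interval <- function(object, data = NULL, ...) {
  band <- tidy(object)
  p <- ggplot(band, aes(x = .data$age)) +
    geom_line(aes(y = .data$lower), linetype = 2) +
    geom_line(aes(y = .data$upper), linetype = 2) +
    facet_wrap(~sex) +
    labs(
      y = "phenotype value",
      title = sprintf("%s %.0f%% reference interval",
                      if (object$calibrated) "Calibrated" else "Naive",
                      100 * (1 - object$alpha))
    ) +
    theme_minimal()
  if (!is.null(data)) {
    pts <- evaluate_membership(object, data)
    p <- p + geom_point(
      data = pts,
      aes(y = .data$value, colour = .data$membership != "inside"),
      alpha = 0.5, size = 0.8
    ) +
      scale_colour_manual(values = c("FALSE" = "steelblue",
                                     "TRUE" = "darkorange"),
                          labels = c("inside", "outside"),
                          name = NULL)
  }
  p
}

#' Plot FPR medians and interquartile ranges across calibration sizes
#'
#' One panel per miscoverage level, calibration size on the x axis, one
#' colour per method, the nominal target as a dashed line — the standard
#' layout for reading off which methods control the false positive rate and
#' from which calibration size onward.
#'
#' @param summary output of [summarize_trials()].
#' @return a ggplot object.
#' @export
plot_fpr_curves <- function(summary) {
  stopifnot(all(c("cal_size", "alpha", "method", "fpr_median") %in%
                  names(summary)))
  ggplot(summary, aes(x = .data$cal_size, colour = .data$method)) +
    geom_hline(aes(yintercept = .data$alpha), linetype = 2,
               colour = "grey40") +
    geom_pointrange(aes(y = .data$fpr_median, ymin = .data$fpr_q25,
                        ymax = .data$fpr_q75),
                    position = position_dodge(width = 8)) +
    geom_line(aes(y = .data$fpr_median)) +
    facet_wrap(~alpha, scales = "free_y",
               labeller = label_both) +
    labs(x = "calibration set size", y = "false positive rate") +
    theme_minimal()
}

#' @export
autoplot.residual_set <- function(object, bins = 30, ...) {
  residual_diagnostics(object, bins = bins)$plot
}
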