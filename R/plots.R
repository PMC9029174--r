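# ggplot2 front-ends for the result types.

#' Observed-versus-predicted plot
#'
#' @param records A prediction-record tibble from [predict_concentrations()].
#' @param which `"population"`, `"individual"`, or `"both"` (facetted).
#' @return A ggplot object with the identity line overlaid.
#' @export
plot_gof <- function(records, which = c("both", "population", "individual")) {
  which <- match.arg(which)
  long <- tidyr::pivot_longer(records, c("pop_pred", "ind_pred"),
                              names_to = "type", values_to = "pred")
  long$type <- ifelse(long$type == "pop_pred", "population", "individual")
  if (which != "both") long <- long[long$type == which, ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$pred, y = .data$obs)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "steelblue", linewidth = 0.6) +
    ggplot2::facet_wrap(~type) +
    ggplot2::labs(x = "Predicted concentration (mg/L)",
                  y = "Observed concentration (mg/L)")
}

#' @rdname autoplot-pippk
#' @export
autoplot.vpc_result <- function(object, ...) {
  ggplot2::ggplot(object$bands, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q05, ymax = .data$q95),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$q50), colour = "steelblue") +
    ggplot2::geom_point(data = object$observations,
                        ggplot2::aes(y = .data$obs, colour = .data$inside)) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "black", `FALSE` = "red"),
                                 guide = "none") +
    ggplot2::labs(x = "Time after dose (h)", y = "Concentration (mg/L)",
                  title = sprintf("Visual predictive check (coverage %.2f)",
                                  object$coverage))
}

#' Autoplot methods for pippk result objects
#'
#' @param object A `vpc_result`, `pta_result`, `bland_altman` or `npag_fit`
#'   object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot-pippk
NULL

#' @rdname autoplot-pippk
#' @export
autoplot.pta_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$mic, y = 100 * .data$pta)) +
    ggplot2::geom_hline(yintercept = 90, linetype = 2, colour = "grey40") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(trans = "log2") +
    ggplot2::labs(x = "MIC (mg/L)", y = "PTA (%)",
                  title = sprintf("%g mg q%gh (%.2g-h infusion), CrCL %g, %g%% fT>MIC",
                                  object$dose[1], object$interval[1],
                                  object$infusion_duration[1], object$crcl[1],
                                  100 * object$target_fraction[1]))
}

#' @rdname autoplot-pippk
#' @export
autoplot.bland_altman <- function(object, ...) {
  d <- attr(object, "differences")
  ylab <- if (object$scale[1] == "percent_of_mean") {
    "Difference (% of pair mean)"
  } else {
    "Difference (mg/L)"
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mean, y = .data$difference)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = object$bias[1], colour = "steelblue") +
    ggplot2::geom_hline(yintercept = c(object$lloa[1], object$uloa[1]),
                        linetype = 2, colour = "grey40") +
    ggplot2::labs(x = "Pair mean (mg/L)", y = ylab)
}

#' @rdname autoplot-pippk
#' @export
autoplot.npag_fit <- function(object, ...) {
  s <- object$support
  ggplot2::ggplot(s, ggplot2::aes(x = .data$CL, y = .data$V,
                                  size = .data$weight)) +
    ggplot2::geom_point(alpha = 0.6, colour = "steelblue") +
    ggplot2::scale_size_area(max_size = 8) +
    ggplot2::labs(x = if (object$use_covariate) "TVCL (L/h)" else "CL (L/h)",
                  y = "V (L)", size = "weight",
                  title = "Nonparametric population support points")
}
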