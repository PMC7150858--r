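#' Plot a mixed logit fit
#'
#' Mean WTP per attribute contrast with approximate 95% normal confidence
#' intervals, and (as bar height annotations) the estimated population
#' standard deviations.
#'
#' @param object An `mxl_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mxl_fit <- function(object, ...) {
  co <- object$coefficients
  means <- co[co$type == "mean", ]
  sds <- co[co$type == "sd", ]
  means$sd <- sds$estimate[match(means$term, sds$term)]
  means$term <- factor(means$term, levels = rev(attribute_scheme()$contrasts))
  ggplot2::ggplot(means, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", color = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$estimate - 1.96 * .data$std_error,
                   xmax = .data$estimate + 1.96 * .data$std_error),
      height = 0.2) +
    ggplot2::geom_point(ggplot2::aes(size = .data$sd)) +
    ggplot2::scale_size_continuous(name = "Population SD (EUR)") +
    ggplot2::labs(
      x = "Mean WTP (EUR per week)", y = NULL,
      title = sprintf("WTP-space mixed logit (%s scenario)", object$scenario),
      subtitle = sprintf("%d respondents, %d %s draws",
                         object$n_respondents, object$spec$n_draws,
                         object$spec$draw_scheme)) +
    ggplot2::theme_minimal()
}

#' Plot a willingness-to-pay summary table
#'
#' Dot-and-interval plot of mean WTP per contrast, faceted by scenario.
#'
#' @param object A [wtp_summary()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.wtp_summary <- function(object, ...) {
  tab <- object[object$attribute != "scale", ]
  tab$term <- factor(tab$term, levels = rev(attribute_scheme()$contrasts))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$mean, y = .data$term,
                                    color = .data$attribute)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", color = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$mean - 1.96 * .data$mean_se,
                   xmax = .data$mean + 1.96 * .data$mean_se),
      height = 0.2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(~scenario) +
    ggplot2::labs(x = "Mean WTP (EUR per week)", y = NULL, color = NULL) +
    ggplot2::theme_minimal()
}
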