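# ---- ggplot2 visualisations ------------------------------------------------

#' Plot per-stratum relative risks for an interaction result
#'
#' Point estimates with 95% confidence intervals on a log-scaled y axis,
#' one point per methylation stratum plus the unstratified "all" column,
#' the usual way stratified triad analyses are displayed.
#'
#' @param object An `interaction_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.interaction_result <- function(object, ...) {
  dat <- object$estimates |>
    dplyr::mutate(stratum = factor(.data$stratum,
                                   levels = c("all",
                                              setdiff(.data$stratum, "all"))))
  ylab <- if (object$analysis == "pooxme") {
    "relative-risk ratio (RR_M / RR_F)"
  } else {
    "relative risk"
  }
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$stratum, y = .data$rr)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$conf.low,
                                          ymax = .data$conf.high)) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "methylation stratum (1 = low)",
      y = ylab,
      title = paste0(toupper(substring(object$analysis, 1, 1)),
                     substring(object$analysis, 2),
                     if (!is.na(object$snp_id))
                       paste0(" - ", object$snp_id) else "",
                     if (!is.na(object$category))
                       paste0(" [", object$category, "]") else ""),
      subtitle = sprintf("Wald interaction p = %.3g, trend p = %.3g",
                         object$wald_p, object$trend_p)
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.interaction_result
#' @param result An `interaction_result`.
#' @export
plot_interaction <- function(result, ...) {
  autoplot(result, ...)
}

#' Quantile-quantile plot with 95% point-wise band
#'
#' Observed vs expected -log10 p-values with the point-wise band from the
#' Beta distribution of uniform order statistics (dashed lines).
#'
#' @param object A `qq_data` tibble from [qq_data()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.qq_data <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$neglog10_expected)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_line(ggplot2::aes(y = .data$neglog10_lower),
                       linetype = "dashed", colour = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$neglog10_upper),
                       linetype = "dashed", colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(y = .data$neglog10_observed),
                        size = 1) +
    ggplot2::labs(x = expression(-log[10] * " expected p"),
                  y = expression(-log[10] * " observed p")) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.qq_data
#' @param p A vector of p-values (passed through [qq_data()]).
#' @export
plot_qq <- function(p, ...) {
  autoplot(qq_data(p), ...)
}
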