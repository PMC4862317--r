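# ggplot2 views of the model and its fits.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the closed-form psychometric function
#'
#' @param v_p,v_r Processing rates in Hz.
#' @param soa_ms SOA grid in ms.
#' @return A ggplot.
#' @export
plot_psychometric <- function(v_p, v_r, soa_ms = seq(-100, 100, 2)) {
  curve <- p_curve(v_p, v_r, soa_ms)
  ggplot2::ggplot(curve, ggplot2::aes(.data$soa_ms, .data$p_probe_first)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "SOA (ms, negative = probe leads)",
                  y = "P(probe judged first)") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' @describeIn plot_psychometric Posterior densities of the group-level
#'   parameters of a fit.
#' @param object A `toj_fit`, `toj_ppc` or `toj_contrast`.
#' @param ... Unused.
#' @method autoplot toj_fit
#' @export
autoplot.toj_fit <- function(object, ...) {
  d <- dplyr::filter(object$draws, .data$parameter %in% group_params)
  ggplot2::ggplot(d, ggplot2::aes(.data$value)) +
    ggplot2::geom_density(fill = "steelblue", alpha = 0.4) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = "posterior draw", y = "density") +
    ggplot2::theme_minimal()
}

#' @method autoplot toj_ppc
#' @export
autoplot.toj_ppc <- function(object, ...) {
  qcols <- grep("^q", names(object), value = TRUE)
  ggplot2::ggplot(object, ggplot2::aes(.data$soa_ms)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data[[qcols[1]]],
                                      ymax = .data[[qcols[length(qcols)]]]),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data[[qcols[ceiling(length(qcols) / 2)]]]),
                       colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed)) +
    ggplot2::labs(x = "SOA (ms)", y = "P(probe judged first)",
                  title = unique(object$condition)) +
    ggplot2::theme_minimal()
}

#' @method autoplot toj_contrast
#' @export
autoplot.toj_contrast <- function(object, ...) {
  ggplot2::ggplot(tibble::tibble(value = object$draws),
                  ggplot2::aes(.data$value)) +
    ggplot2::geom_density(fill = "tomato", alpha = 0.4) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::geom_vline(xintercept = c(object$summary$hdi_low,
                                       object$summary$hdi_high),
                        linetype = 3) +
    ggplot2::labs(x = object$type, y = "density") +
    ggplot2::theme_minimal()
}
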