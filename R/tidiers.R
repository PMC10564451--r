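#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an ICC fit
#'
#' @param x An `icc_fit` from [icc_2_1()].
#' @param ... Unused.
#' @return One-row tibble: `estimate`, `conf.low`, `conf.high`, `category`.
#' @export
tidy.icc_fit <- function(x, ...) {
  tibble::tibble(estimate = x$icc, conf.low = x$ci_low, conf.high = x$ci_high,
                 category = x$category)
}

#' @rdname tidy.icc_fit
#' @return For `glance()`: one-row tibble with the ANOVA mean squares and
#'   design size.
#' @export
glance.icc_fit <- function(x, ...) {
  tibble::tibble(icc = x$icc, msr = x$msr, msc = x$msc, mse = x$mse,
                 n = x$n, k = x$k, alpha = x$alpha)
}

#' Tidy a Bland-Altman analysis
#'
#' @param x A `bland_altman` object.
#' @param ... Unused.
#' @return For `tidy()`: the per-pair means and differences. For `glance()`:
#'   one-row summary (`bias`, `sd_diff`, `loa_low`, `loa_high`, `n`).
#' @export
tidy.bland_altman <- function(x, ...) x$data

#' @rdname tidy.bland_altman
#' @export
glance.bland_altman <- function(x, ...) {
  tibble::tibble(bias = x$bias, sd_diff = x$sd_diff,
                 loa_low = x$loa_low, loa_high = x$loa_high, n = x$n)
}

#' Bland-Altman plot
#'
#' Difference against pair mean, with the bias line (solid) and the limits
#' of agreement (dashed).
#'
#' @param object A `bland_altman` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = object$bias, linewidth = 0.6) +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed") +
    ggplot2::labs(x = "Mean of paired measurements",
                  y = "Difference between measurements",
                  title = sprintf("Bland-Altman: bias %.3f, LoA [%.3f, %.3f]",
                                  object$bias, object$loa_low,
                                  object$loa_high)) +
    ggplot2::theme_minimal()
}

#' Occlusal-view plot of a movement table
#'
#' Bar chart of signed movement values per tooth, faceted by movement type.
#'
#' @param movements A movement-record tibble from [measure_arch()].
#' @return A ggplot.
#' @export
plot_movements <- function(movements) {
  ok <- movements[movements$status == "ok", ]
  ggplot2::ggplot(ok, ggplot2::aes(x = .data$tooth_id, y = .data$value)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~movement, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "Signed movement (mm or degrees)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
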