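# ggplot2 display methods for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Plot a weight density
#'
#' @param object A [weight_density()] object.
#' @param trim Drop grid cells with density below `trim` times the maximum
#'   at the plot edges (the default grid is much wider than the support).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dw_density <- function(object, trim = 1e-8, ...) {
  df <- tibble::as_tibble(object)
  keep <- which(df$density > trim * max(df$density))
  if (length(keep) > 1) df <- df[min(keep):max(keep), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$J, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "synaptic strength J", y = "density g(J)")
}

#' Plot an SNR curve
#'
#' @param object A `dw_snr` tibble from [snr_double_well()].
#' @param ... Unused.
#' @return A ggplot with a log-scaled SNR axis.
#' @export
autoplot.dw_snr <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$age, y = .data$snr)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "age (presentations)", y = "SNR")
}

#' Plot the overlap-vs-age curve of a capacity result
#'
#' @param object A `dw_capacity` object.
#' @param ages Ages to display (default up to just past the capacity).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dw_capacity <- function(object, ages = NULL, ...) {
  df <- tidy(object, ages = ages)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$age, y = .data$m_v)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$p, linetype = "dashed") +
    ggplot2::labs(x = "pattern age u - v", y = "overlap m_v")
}

#' Plot a capacity-vs-width search
#'
#' @param object A `dw_copt` object from [optimize_C()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dw_copt <- function(object, ...) {
  ggplot2::ggplot(object$table, ggplot2::aes(x = .data$C, y = .data$p)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$C_star, linetype = "dashed") +
    ggplot2::labs(x = "potential half-width C", y = "storage capacity p")
}

#' Plot a capacity-vs-noise robustness table
#'
#' @param object A `dw_robustness` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dw_robustness <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = .data$r3_tilde, y = .data$p)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "normalized noise r3 / Omega", y = "storage capacity p")
}

#' Plot a capacity scaling fit
#'
#' @param object A `dw_scaling` object from [fit_scaling_exponent()].
#' @param ... Unused.
#' @return A log-log ggplot of the data with the fitted power law.
#' @export
autoplot.dw_scaling <- function(object, ...) {
  df <- object$data
  df$fit <- object$prefactor * df$N^object$exponent
  ggplot2::ggplot(df, ggplot2::aes(x = .data$N)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$p)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fit)) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "network size N", y = "storage capacity p")
}
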