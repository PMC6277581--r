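# ggplot2 graphics for melt profiles, electropherograms and screen results

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_rect
#'   geom_jitter labs theme_minimal facet_wrap
#' @export
ggplot2::autoplot

#' Plot -dF/dT melt peak profiles
#'
#' @param curves Melt-curve tibble (raw fluorescence); transformed with
#'   [melt_derivative()] before plotting.
#' @param window,degree Smoothing parameters, as in [melt_derivative()].
#' @return A ggplot object: one -dF/dT trace per sample.
#' @export
plot_melt_profiles <- function(curves, window = 7, degree = 2) {
  d <- melt_derivative(curves, window = window, degree = degree)
  ggplot(d, aes(x = .data$temperature, y = .data$neg_deriv, colour = .data$sample_id)) +
    geom_line() +
    labs(
      x = "Temperature (°C)", y = "-dF/dT",
      colour = "Sample", title = "TP-PCR melt peak profiles"
    ) +
    theme_minimal()
}

#' Plot a CE electropherogram
#'
#' @param trace Electropherogram tibble from [simulate_tppcr_trace()] or
#'   [simulate_regular_trace()].
#' @return A ggplot object, faceted by sample.
#' @export
plot_trace <- function(trace) {
  dialect <- attr(trace, "dialect") %||% "trace"
  ggplot(trace, aes(x = .data$size_bp, y = .data$intensity)) +
    geom_line(linewidth = 0.3) +
    facet_wrap(~sample_id, scales = "free_y") +
    labs(
      x = "Fragment size (bp)", y = "Intensity",
      title = paste0("CE electropherogram (", dialect, ")")
    ) +
    theme_minimal()
}

#' Tm strip chart of a cohort screen
#'
#' Last-peak Tm of every analyzable sample against the calibrated IM/GZ
#' boundary band, coloured by final call: the visual form of the screen's
#' decision rule.
#'
#' @param object An `fxs_screen` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fxs_screen <- function(object, ...) {
  rec <- object$records |> filter(!is.na(.data$tm))
  b <- object$boundary
  ggplot(rec, aes(x = .data$sex, y = .data$tm, colour = .data$final_call)) +
    geom_rect(
      xmin = -Inf, xmax = Inf,
      ymin = b$lower_tm - b$margin, ymax = b$upper_tm + b$margin,
      fill = "grey85", colour = NA, alpha = 0.4
    ) +
    geom_jitter(width = 0.15, height = 0, size = 1.5) +
    labs(
      x = "Sex", y = expression(T[m] ~ (degree * C)), colour = "Final call",
      title = "Last-peak Tm vs IM/GZ boundary"
    ) +
    theme_minimal()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
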