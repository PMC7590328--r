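# broom-style accessors and ggplot2 visualisation.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted kinetic model
#'
#' One row per estimated parameter, with its unit.
#'
#' @param x A `ferm_fit` from [fit_growth()] or [fit_product()].
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `unit`.
#' @exportS3Method generics::tidy
tidy.ferm_fit <- function(x, ...) {
  tibble::tibble(term = names(x$estimates),
                 estimate = unname(x$estimates),
                 unit = unname(x$units[names(x$estimates)]))
}

#' Glance at a fitted kinetic model
#'
#' @param x A `ferm_fit`.
#' @param ... Unused.
#' @return A one-row tibble: model identity, the goodness-of-fit
#'   battery, convergence flag and iteration count.
#' @exportS3Method generics::glance
glance.ferm_fit <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(model = x$model, type = x$type), x$gof,
                   tibble::tibble(converged = x$converged, n_iter = x$n_iter))
}

#' Plot a fitted kinetic model over its data
#'
#' Observed points and the fitted curve on the fit window. Growth fits
#' are drawn on the log10(N/N0) scale, product fits in g/L.
#'
#' @param object A `ferm_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ferm_fit <- function(object, ...) {
  ylab <- if (object$type == "growth") "log10(N/N0)" else "lactic acid (g/L)"
  ggplot2::ggplot(object$predicted, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$predicted), colour = "#2166ac") +
    ggplot2::labs(
      x = paste0("time (", object$time_unit %||% "hr", ")"), y = ylab,
      title = sprintf("%s fit (%s)", object$model,
                      if (object$converged) "converged" else "not converged"),
      subtitle = sprintf("R2 = %.4f, RMSE = %.4g", object$gof$r2_uncentered,
                         object$gof$rmse)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a fermentation series
#'
#' Faceted trajectory of the available channels: viable counts (log10
#' scale), titratable acidity, and pH against time.
#'
#' @param data Series tibble with a `time` column and any of `cfu`,
#'   `acidity`, `pH`.
#' @return A ggplot object.
#' @export
plot_series <- function(data) {
  if (!is.data.frame(data) || !"time" %in% names(data)) {
    stop("`data` must contain a `time` column.", call. = FALSE)
  }
  chans <- intersect(c("cfu", "acidity", "pH"), names(data))
  if (!length(chans)) stop("no data channels to plot.", call. = FALSE)
  long <- tidyr::pivot_longer(data[c("time", chans)], -"time",
                              names_to = "channel", values_to = "value")
  long$value[long$channel == "cfu"] <- log10(long$value[long$channel == "cfu"])
  long$channel <- factor(long$channel, levels = c("cfu", "acidity", "pH"),
                         labels = c("log10 cfu/g", "acidity (g/L)", "pH"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::facet_wrap(~channel, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (hr)", y = NULL) +
    ggplot2::theme_minimal()
}
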