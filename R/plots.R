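#' Plot methods
#'
#' `autoplot()` methods give quick ggplot2 views of the pipeline objects:
#' the absorbance surface of a chromatogram, the observed/fitted traces of
#' an elution-model fit, the PCA scores and clusters of a species-count
#' estimate, and the resolved spectra and concentration profiles of a curve
#' resolution.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot.
#' @name chromaspec-autoplot
NULL

#' @rdname chromaspec-autoplot
#' @export
autoplot.spectral_chromatogram <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$time, .data$wavelength,
                               fill = .data$absorbance)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "A (AU)") +
    ggplot2::labs(x = "time (min)", y = "wavelength (nm)") +
    ggplot2::theme_minimal()
}

#' @rdname chromaspec-autoplot
#' @export
autoplot.channel_chromatogram <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$time, .data$absorbance)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (min)", y = "absorbance (AU)",
                  title = sprintf("%g +/- %g nm", object$center_wavelength,
                                  object$half_window)) +
    ggplot2::theme_minimal()
}

#' @rdname chromaspec-autoplot
#' @export
autoplot.gmm_fit <- function(object, ...) {
  df <- if (is.null(object$observed)) {
    # shared-Rt fit: show the component concentration profiles
    k <- ncol(object$C)
    tibble(time = rep(object$time, k),
           trace = rep(sprintf("component %d", seq_len(k)),
                       each = length(object$time)),
           absorbance = as.vector(object$C))
  } else {
    tidyr::pivot_longer(
      tibble(time = object$time, observed = object$observed,
             fitted = object$fitted),
      -"time", names_to = "trace", values_to = "absorbance")
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$absorbance,
                                   colour = .data$trace)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$components$rt,
                        linetype = "dashed", alpha = 0.5) +
    ggplot2::labs(x = "time (min)", y = "absorbance (AU)") +
    ggplot2::theme_minimal()
}

#' @rdname chromaspec-autoplot
#' @export
autoplot.clustering_result <- function(object, ...) {
  df <- as_tibble(object$scores, .name_repair = ~ paste0("PC", seq_along(.x)))
  df$cluster <- factor(object$labels)
  centers <- as_tibble(object$centers,
                       .name_repair = ~ paste0("PC", seq_along(.x)))
  ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2,
                                   colour = .data$cluster)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_point(data = centers, colour = "black", shape = 1,
                        size = 4, stroke = 1.2) +
    ggplot2::labs(title = sprintf("k = %d (elbow)", object$k)) +
    ggplot2::theme_minimal()
}

#' @rdname chromaspec-autoplot
#' @param type For MCR results: `"spectra"` or `"profiles"`.
#' @export
autoplot.mcr_result <- function(object, type = c("spectra", "profiles"), ...) {
  type <- match.arg(type)
  M <- if (type == "spectra") object$S else object$C
  df <- as_tibble(M, .name_repair = ~ sprintf("component %d", seq_along(.x)))
  df$index <- seq_len(nrow(M))
  df <- tidyr::pivot_longer(df, -"index", names_to = "component",
                            values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$index, .data$value,
                                   colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = if (type == "spectra") "wavelength index" else "time index",
      y = if (type == "spectra") "absorbance (unit max)" else "concentration (AU)") +
    ggplot2::theme_minimal()
}

#' Plot a detection channel with annotated peaks
#'
#' @param channel A `channel_chromatogram`.
#' @param peaks Optional peak table from [detect_peaks()].
#' @return A ggplot.
#' @export
plot_peaks <- function(channel, peaks = NULL) {
  p <- autoplot(channel)
  if (!is.null(peaks) && nrow(peaks)) {
    p <- p + ggplot2::geom_point(
      data = peaks,
      ggplot2::aes(.data$apex_time, .data$apex_absorbance),
      inherit.aes = FALSE, shape = 25, fill = "red", size = 2)
  }
  p
}
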