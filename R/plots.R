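#' Forest plot of OPERA estimates across the model grid
#'
#' Plots log OPERA point estimates with 95% confidence intervals for every
#' measure, scale and outcome, univariable and multivariable models side by
#' side -- the standard way to eyeball which measure's association survives
#' joint modelling.
#'
#' @param object An `opera_grid` from [run_model_grid()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.opera_grid <- function(object, ...) {
  uni <- dplyr::mutate(object$univariable, model = "univariable")
  multi <- object$multivariable
  dat <- dplyr::bind_rows(
    dplyr::select(uni, "outcome", "scale", "model", "measure",
                  "log_opera", "conf.low", "conf.high"),
    dplyr::select(multi, "outcome", "scale", "model", "measure",
                  "log_opera", "conf.low", "conf.high")
  )
  dat <- dplyr::mutate(
    dat,
    conf.low = log(.data$conf.low),
    conf.high = log(.data$conf.high),
    model = factor(.data$model, levels = unique(.data$model))
  )
  ggplot2::ggplot(
    dat,
    ggplot2::aes(x = .data$model, y = .data$log_opera, colour = .data$measure)
  ) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$conf.low, ymax = .data$conf.high),
      position = ggplot2::position_dodge(width = 0.5), size = 0.3
    ) +
    ggplot2::facet_grid(scale ~ outcome) +
    ggplot2::labs(x = NULL, y = "log OPERA (95% CI)", colour = "measure") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Display a grayscale image with measured density regions
#'
#' Raster view of a [gray_image()] with optional contour-free overlays of
#' the breast (background threshold) and dense (density threshold)
#' superlevel regions.
#'
#' @param object A [gray_image()].
#' @param thr Optional [threshold_pair()] whose superlevel regions are
#'   tinted.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gray_image <- function(object, thr = NULL, ...) {
  df <- expand.grid(
    row = seq_len(nrow(object$pixels)),
    col = seq_len(ncol(object$pixels))
  )
  df$intensity <- as.vector(object$pixels)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  if (!is.null(thr)) {
    df$region <- ifelse(
      df$intensity >= thr$density_threshold, "dense",
      ifelse(df$intensity >= thr$background_threshold, "breast", NA)
    )
    p <- p + ggplot2::geom_raster(
      data = df[!is.na(df$region), ],
      ggplot2::aes(alpha = .data$region), fill = "green"
    ) +
      ggplot2::scale_alpha_manual(values = c(breast = 0.15, dense = 0.45))
  }
  p
}

#' Plot repeated-measurement agreement
#'
#' Scatter of second versus first measurement for repeat pairs, with the
#' identity line; a visual companion to the [icc()] estimate.
#'
#' @param data A tibble from [generate_repeat_measurements()] (columns
#'   `pair_id`, `replicate`, `value`).
#' @return A ggplot object.
#' @export
plot_repeatability <- function(data) {
  wide <- tidyr::pivot_wider(
    dplyr::filter(data, .data$replicate <= 2L),
    names_from = "replicate", values_from = "value", names_prefix = "m"
  )
  ggplot2::ggplot(wide, ggplot2::aes(x = .data$m1, y = .data$m2)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::labs(x = "first measurement", y = "repeat measurement") +
    ggplot2::theme_bw()
}
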