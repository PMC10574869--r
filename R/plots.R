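#' Plot a radiograph with optional landmark overlay
#'
#' @param img A [radiograph].
#' @param landmarks Optional tibble `poi_id, x, y` drawn over the image.
#' @param downsample Keep every n-th pixel for display speed (default 2).
#' @return A ggplot object (y axis reversed: raster convention).
#' @export
plot_radiograph <- function(img, landmarks = NULL, downsample = 2) {
  stopifnot(inherits(img, "radiograph"))
  px <- img$pixels
  ri <- seq(1, nrow(px), by = downsample)
  ci <- seq(1, ncol(px), by = downsample)
  df <- expand.grid(y = ri - 1, x = ci - 1)
  df$intensity <- as.vector(px[ri, ci])
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 255)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = img$image_id, x = "x (px)", y = "y (px)") +
    ggplot2::theme_minimal()
  if (!is.null(landmarks)) {
    p <- p +
      ggplot2::geom_point(data = landmarks, color = "red", size = 2) +
      ggplot2::geom_text(data = landmarks,
                         ggplot2::aes(label = .data$poi_id),
                         color = "yellow", nudge_x = 18, size = 3)
  }
  p
}

#' @export
autoplot.threshold_sweep <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$threshold, .data$mean_localization)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "similarity threshold",
                  y = "mean localization score 1/(1+d)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.dataset_evaluation <- function(object, ...) {
  long <- tidyr::pivot_longer(object$metrics, -"class",
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$class, .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = NULL, y = "percent") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.foot_diagnosis <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$angle, .data$value,
                                   fill = .data$vote)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "degrees",
                  title = paste("final:", object$final)) +
    ggplot2::theme_minimal()
}
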