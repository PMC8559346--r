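#' Plot a ROC curve
#'
#' @param object a `glom_roc` tibble from [roc_curve()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.glom_roc <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate (1 - specificity)",
                  y = "True positive rate (sensitivity)",
                  title = "ROC curve") +
    ggplot2::theme_minimal()
}

#' Plot the hidden-size selection trace
#'
#' Mean cross-validated MCC and accuracy against the number of hidden
#' units, with the selected size marked.
#'
#' @param object a `glom_size_sweep` from [select_hidden_size()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.glom_size_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(object$trace, -"hidden_size",
                              names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$hidden_size,
                                     y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(xintercept = object$best_size,
                        linetype = "dotted") +
    ggplot2::labs(x = "Hidden layer size", y = NULL,
                  title = "Cross-validated hidden-size sweep",
                  subtitle = sprintf("selected size: %d", object$best_size)) +
    ggplot2::theme_minimal()
}

#' Display a glomerulus crop, optionally with its mask outline
#'
#' @param img H x W x 3 array, 8-bit intensities.
#' @param mask optional logical mask drawn as a semi-transparent overlay.
#' @return a ggplot object.
#' @export
plot_crop <- function(img, mask = NULL) {
  assert_raster(img)
  H <- dim(img)[1]; W <- dim(img)[2]
  df <- tibble(
    x = rep(seq_len(W), each = H),
    y = rep(seq_len(H), times = W),
    fill = grDevices::rgb(as.vector(img[, , 1]), as.vector(img[, , 2]),
                          as.vector(img[, , 3]), maxColorValue = 255)
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
  if (!is.null(mask)) {
    md <- df[as.vector(as_mask(mask)), c("x", "y")]
    p <- p + ggplot2::geom_raster(data = md, fill = "cyan", alpha = 0.25)
  }
  p
}
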