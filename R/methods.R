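#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an evaluation sweep
#'
#' @param x an `eval_curves` object from [pr_curve()].
#' @param ... unused.
#' @return A plain tibble of the threshold sweep (one row per threshold).
#' @method tidy eval_curves
#' @export
tidy.eval_curves <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' One-row summary of an evaluation sweep
#'
#' @param x an `eval_curves` object.
#' @param ... unused.
#' @return A one-row tibble with `roc_area` and the number of thresholds.
#' @method glance eval_curves
#' @export
glance.eval_curves <- function(x, ...) {
  tibble::tibble(roc_area = attr(x, "roc_area"), n_thresholds = nrow(x))
}

#' Tidy a detection result
#'
#' @param x a `detection_result` from [extract_moving_objects()].
#' @param ... unused.
#' @return The tibble of predicted boxes.
#' @method tidy detection_result
#' @export
tidy.detection_result <- function(x, ...) x$boxes

#' One-row summary of a detection result
#'
#' @param x a `detection_result`.
#' @param ... unused.
#' @return A one-row tibble: number of boxes, foreground pixel count and
#'   foreground fraction.
#' @method glance detection_result
#' @export
glance.detection_result <- function(x, ...) {
  tibble::tibble(n_boxes = nrow(x$boxes), n_foreground = sum(x$mask),
                 foreground_fraction = mean(x$mask))
}

#' Plot a saliency map
#'
#' @param object a `saliency_map`.
#' @param ... unused.
#' @return A ggplot raster of the map.
#' @method autoplot saliency_map
#' @export
autoplot.saliency_map <- function(object, ...) {
  df <- expand.grid(y = seq_len(nrow(object)), x = seq_len(ncol(object)))
  df$saliency <- as.vector(unclass(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$saliency)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::theme_void() +
    ggplot2::labs(fill = "saliency")
}

#' Plot an evaluation sweep
#'
#' @param object an `eval_curves` object.
#' @param type `"pr"` for precision-recall, `"roc"` for the ROC curve.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot eval_curves
#' @export
autoplot.eval_curves <- function(object, type = c("pr", "roc"), ...) {
  type <- match.arg(type)
  df <- tibble::as_tibble(unclass(object))
  if (type == "pr") {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$recall, y = .data$precision)) +
      ggplot2::geom_path() +
      ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
      ggplot2::labs(x = "recall", y = "precision") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
      ggplot2::geom_path() +
      ggplot2::geom_abline(linetype = 3) +
      ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
      ggplot2::labs(x = "false positive rate", y = "true positive rate",
                    subtitle = sprintf("ROC area = %.4f", attr(object, "roc_area"))) +
      ggplot2::theme_minimal()
  }
}
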