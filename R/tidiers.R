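# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' Tidy a LOSO evaluation
#'
#' @param x a `cmer_eval` from [evaluate_loso()] or [run_pipeline()].
#' @param ... unused.
#' @return Tibble with one row per (truth, predicted) cell of the pooled
#'   confusion matrix: `truth, pred, n, prop` (row-normalised proportion).
#' @export
tidy.cmer_eval <- function(x, ...) {
  cm <- as.matrix(x$confusion)
  df <- as_tibble(as.data.frame(as.table(cm), stringsAsFactors = FALSE))
  names(df) <- c("truth", "pred", "n")
  totals <- rowSums(cm)[df$truth]
  df$prop <- ifelse(totals > 0, df$n / totals, 0)
  df
}

#' @rdname tidy.cmer_eval
#' @return `glance()`: one-row tibble `accuracy, f1, n, n_subjects,
#'   n_classes`.
#' @export
glance.cmer_eval <- function(x, ...) {
  tibble(accuracy = x$accuracy, f1 = x$f1, n = nrow(x$predictions),
         n_subjects = nrow(x$per_fold), n_classes = length(x$class_levels))
}

#' Tidy a trained classifier's loss curve
#'
#' @param x a `cmer_cnn`; @param ... unused.
#' @return Tibble `epoch, loss, lr` (epoch 0 is the pre-training loss).
#' @export
tidy.cmer_cnn <- function(x, ...) {
  if (is.null(x$loss_curve)) abort("model is untrained")
  ep <- seq_along(x$loss_curve) - 1L
  tibble(epoch = ep, loss = x$loss_curve,
         lr = c(NA, learning_rate_schedule(ep[-1] - 1L)))
}

#' Plot a confusion matrix heat map
#'
#' @param object a `cmer_eval`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.cmer_eval <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pred, y = .data$truth,
                                   fill = .data$prop)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1)) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(x = "predicted", y = "true", fill = "row prop.",
                  title = sprintf("LOSO accuracy %.1f%%, macro F1 %.3f",
                                  100 * object$accuracy, object$f1)) +
    ggplot2::theme_minimal()
}

#' Plot a flow field as its colour-coded feature map
#'
#' @param object a [flow_field()].
#' @param max_mag see [flow_to_feature_map()].
#' @param ... unused.
#' @return A ggplot object (raster of the colour wheel encoding).
#' @export
autoplot.flow_field <- function(object, max_mag = "auto", ...) {
  rgb_arr <- flow_to_feature_map(object, max_mag)
  H <- dim(rgb_arr)[1]; W <- dim(rgb_arr)[2]
  df <- tibble(
    x = rep(seq_len(W), each = H), y = rep(seq_len(H), times = W),
    col = grDevices::rgb(as.vector(rgb_arr[, , 1]),
                         as.vector(rgb_arr[, , 2]),
                         as.vector(rgb_arr[, , 3])))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$col)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}

#' Plot a training loss curve
#'
#' @param object a trained `cmer_cnn`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.cmer_cnn <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "epoch", y = "training loss") +
    ggplot2::theme_minimal()
}
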