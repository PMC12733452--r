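#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidiers for fitted segmentation models
#'
#' `tidy()` returns the per-epoch training history; `glance()` a one-row
#' summary of the run.
#'
#' @param x a [train()] result.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.sonoseg_fit <- function(x, ...) x$history

#' @rdname tidy.sonoseg_fit
#' @export
glance.sonoseg_fit <- function(x, ...) {
  tibble::tibble(architecture = x$model$spec$architecture,
                 epochs = nrow(x$history),
                 best_epoch = x$best_epoch,
                 best_val_dice = x$best_val_dice,
                 stopped_early = x$stopped_early,
                 final_lr = x$history$lr[nrow(x$history)],
                 parameters = count_trainable_parameters(x$model))
}

#' Tidiers for metric reports
#'
#' `tidy()` returns the per-slice metric table; `glance()` the macro
#' aggregate.
#'
#' @param x an [evaluate()] result.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.sonoseg_metric_report <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x))
}

#' @rdname tidy.sonoseg_metric_report
#' @export
glance.sonoseg_metric_report <- function(x, ...) {
  ag <- attr(x, "aggregate")
  tibble::tibble(mean_dice = ag$mean_dice, mean_iou = ag$mean_iou,
                 mean_accuracy = ag$mean_accuracy, n_slices = ag$n_slices)
}

#' Tidier for anomaly reports
#'
#' @param x an [anomaly_report()] result.
#' @param ... unused.
#' @return the region tibble.
#' @export
tidy.sonoseg_anomaly_report <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x$regions))
}

#' Plot a training history
#'
#' Loss and validation Dice per epoch, with the learning-rate steps.
#'
#' @param object a [train()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.sonoseg_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history,
                           c("loss", "val_dice", "lr"),
                           names_to = "series", values_to = "value")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "epoch", y = NULL,
                  title = sprintf("Training history (%s)",
                                  object$model$spec$architecture)) +
    ggplot2::theme_minimal()
}

#' Plot per-slice metric distributions
#'
#' @param object an [evaluate()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.sonoseg_metric_report <- function(object, ...) {
  d <- tidyr::pivot_longer(tibble::as_tibble(as.data.frame(object)),
                           c("dice", "iou", "accuracy"),
                           names_to = "metric", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "per-slice value") +
    ggplot2::theme_minimal()
}

#' Plot a spectrogram
#'
#' Log-magnitude short-time spectrum of a sonification.
#'
#' @param object a [compute_spectrogram()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.sonoseg_spectrogram <- function(object, ...) {
  d <- expand.grid(freq_hz = object$freq_hz, time_s = object$time_s)
  d$db <- 20 * log10(as.vector(object$magnitude) + 1e-12)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_s, y = .data$freq_hz,
                                  fill = .data$db)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)", fill = "dB") +
    ggplot2::theme_minimal()
}

#' Piano-roll plot of a MIDI sequence
#'
#' @param object a [create_advanced_midi_from_brain()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.sonoseg_midi <- function(object, ...) {
  ev <- object$events
  ggplot2::ggplot(ev, ggplot2::aes(xmin = .data$onset_beats,
                                   xmax = .data$onset_beats +
                                     .data$duration_beats,
                                   ymin = .data$pitch - 0.4,
                                   ymax = .data$pitch + 0.4,
                                   fill = .data$velocity)) +
    ggplot2::geom_rect() +
    ggplot2::scale_fill_viridis_c(limits = c(1, 127)) +
    ggplot2::labs(x = "beats", y = "MIDI pitch", fill = "velocity") +
    ggplot2::theme_minimal()
}
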