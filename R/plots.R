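# ggplot2 views of the main result types.

#' @export
autoplot.binned_signal <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = (.data$start + .data$end) / 2, y = .data$value)) +
    ggplot2::geom_step() +
    ggplot2::labs(
      x = sprintf("%s position (bp)", object$region$chrom),
      y = "log(1 + mean coverage)",
      title = sprintf("Binned signal, %d bp bins", object$bin_size)
    )
}

#' @export
autoplot.note_sequence <- function(object, ...) {
  ev <- object$events
  notes <- ev[ev$kind == "note", , drop = FALSE]
  p <- ggplot2::ggplot() +
    ggplot2::labs(x = "tick", y = "MIDI pitch", title = "Piano roll")
  if (nrow(notes) > 0L) {
    p <- p + ggplot2::geom_segment(
      data = notes,
      ggplot2::aes(x = .data$start_tick, xend = .data$start_tick + .data$duration_ticks,
                   y = .data$pitch, yend = .data$pitch),
      linewidth = 2
    )
  }
  p
}

#' @export
autoplot.distance_matrix <- function(object, ...) {
  df <- tidyr::expand_grid(a = object$labels, b = object$labels)
  df$distance <- as.vector(t(object$values))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$b, fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = "Hausdorff\ndistance") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' @export
autoplot.grid_search_result <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = factor(.data$n_mfcc), y = factor(.data$n_gmm),
                               fill = .data$auc)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.3f", .data$auc)), color = "white") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "MFCC coefficients", y = "GMM components", fill = "AUC")
}

#' @export
autoplot.roc_result <- function(object, ...) {
  abort("autoplot.roc_result needs the underlying scores; use autoplot on a scored tibble instead")
}

#' ROC curve of per-locus D scores
#'
#' @param scored Tibble with columns `D` and `label`, e.g. from
#'   [score_de_scenario()].
#' @return A ggplot object.
#' @export
plot_roc <- function(scored) {
  stopifnot(all(c("D", "label") %in% names(scored)))
  ord <- order(scored$D, decreasing = TRUE)
  lab <- as.integer(as.logical(scored$label))[ord]
  df <- tibble::tibble(
    fpr = c(0, cumsum(1 - lab) / sum(1 - lab)),
    tpr = c(0, cumsum(lab) / sum(lab))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = "dashed", color = "grey60") +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = "ROC of D statistic vs differential labels")
}
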