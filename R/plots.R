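# ggplot2 helpers for the main result types.

#' Plot a per-cell score distribution with its threshold
#'
#' @param scores Score table (tibble with `auc_score`), optionally
#'   stratified.
#' @param threshold Optional number or `pcd_threshold` to mark.
#' @param by Optional column name to facet by (e.g. `"group"`).
#' @return A ggplot object.
#' @export
plot_score_distribution <- function(scores, threshold = NULL, by = NULL) {
  stopifnot(is.data.frame(scores), "auc_score" %in% names(scores))
  p <- ggplot2::ggplot(scores, ggplot2::aes(x = .data$auc_score)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey40") +
    ggplot2::labs(x = "panel activity score (recovery-curve AUC)", y = "cells")
  if (!is.null(threshold)) {
    if (inherits(threshold, "pcd_threshold")) threshold <- threshold$threshold
    p <- p + ggplot2::geom_vline(xintercept = threshold, colour = "firebrick",
                                 linetype = "dashed")
  }
  if (!is.null(by)) p <- p + ggplot2::facet_wrap(stats::as.formula(paste("~", by)))
  p
}

#' @describeIn detect_threshold Density plot of the score distribution with
#'   detected modes and the threshold.
#' @param object A `pcd_threshold`.
#' @param ... Unused.
#' @export
autoplot.pcd_threshold <- function(object, ...) {
  d <- tibble(x = object$density$x, y = object$density$y)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$threshold, colour = "firebrick",
                        linetype = "dashed") +
    ggplot2::labs(x = "score", y = "density",
                  title = sprintf("threshold %.4f (%s)", object$threshold, object$method))
  modes <- object$diagnostics$modes
  if (nrow(modes) > 0) {
    p <- p + ggplot2::geom_point(data = modes,
                                 ggplot2::aes(x = .data$x, y = .data$density),
                                 colour = "steelblue", size = 2)
  }
  p
}

#' Plot per-cell-type group slopes with confidence intervals
#'
#' @param slopes A `pcd_slopes` tibble from [group_slope()].
#' @return A ggplot object.
#' @export
plot_slopes <- function(slopes) {
  stopifnot(is.data.frame(slopes), all(c("cell_type", "slope") %in% names(slopes)))
  ggplot2::ggplot(slopes, ggplot2::aes(x = stats::reorder(.data$cell_type, .data$slope),
                                       y = .data$slope)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "score slope (injured - baseline)")
}

#' Plot a consensus connectivity screen
#'
#' @param consensus Output of [consensus_screen()].
#' @param top Number of compounds to show (default 20, strongest reversers
#'   first).
#' @return A ggplot object.
#' @export
plot_connectivity <- function(consensus, top = 20) {
  stopifnot(is.data.frame(consensus),
            all(c("compound", "mean_scaled", "retained") %in% names(consensus)))
  dat <- head(arrange(consensus, .data$mean_scaled), top)
  ggplot2::ggplot(dat, ggplot2::aes(x = stats::reorder(.data$compound, -.data$mean_scaled),
                                    y = .data$mean_scaled, fill = .data$retained)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick", `FALSE` = "grey60")) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "mean scaled connectivity score",
                  fill = "consensus\nreverser")
}
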