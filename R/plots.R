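# ggplot2 views of the package's result objects.

#' Plot an optimizer run log
#'
#' Fitness trajectories (per-generation best and mean, plus the archived
#' best-ever score) and, when the run tracked ground truth, the matched IoU
#' of the best individual.
#'
#' @param object An `evoseg_run` from [run_evolution()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.evoseg_run <- function(object, ...) {
  log <- object$log
  long <- rbind(
    tibble(generation = log$generation, value = log$best_score,
           series = "best score"),
    tibble(generation = log$generation, value = log$mean_score,
           series = "mean score"),
    tibble(generation = log$generation, value = log$best_ever,
           series = "best ever"))
  if (!all(is.na(log$matched_iou)))
    long <- rbind(long, tibble(generation = log$generation,
                               value = log$matched_iou,
                               series = "matched IoU (best)"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$generation, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "generation", y = NULL, colour = NULL,
                  title = sprintf("Evolutionary segmentation (%s replacement)",
                                  object$config$replacement)) +
    ggplot2::theme_minimal()
}

#' Plot a ROC curve
#'
#' @param object A `roc_curve` from [evaluate_roc()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("ROC (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' Plot one z-slice of a density map or label map
#'
#' @param x A [density_map()] or [label_map()].
#' @param z Slice index (defaults to the middle section).
#' @return A ggplot raster of the slice.
#' @export
plot_slice <- function(x, z = NULL) {
  grid <- if (inherits(x, "density_map")) x$grid
          else if (inherits(x, "label_map")) x$labels
          else stop("`x` must be a density_map or label_map", call. = FALSE)
  d <- dim(grid)
  z <- z %||% ceiling(d[3] / 2)
  stopifnot(z >= 1, z <= d[3])
  df <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]))
  df$value <- as.vector(grid[, , z])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y))
  if (inherits(x, "label_map")) {
    df$value <- factor(df$value)
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
      ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
      ggplot2::labs(fill = "segment")
  } else {
    p <- p + ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
      ggplot2::scale_fill_viridis_c() +
      ggplot2::labs(fill = "density")
  }
  p + ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("z = %d", z)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
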