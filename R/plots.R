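# ggplot2 autoplot methods for the result types

#' Plot a depth profile as sliding-window coverage tracks
#'
#' Total ("normal") and unique coverage as mean depth over a sliding
#' window, the standard view for judging where unique mappability collapses
#' across duplicated blocks.
#'
#' @param object A [depth_profile()].
#' @param window Sliding-window size in bp (default the published 300).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot depth_profile
#' @export
autoplot.depth_profile <- function(object,
                                   window = window_params()$coverage_window,
                                   ...) {
  track <- sliding_mean_depth(object, window = window)
  long <- tidyr::pivot_longer(track, c("total_mean", "unique_mean"),
                              names_to = "track", values_to = "depth")
  long$track <- ifelse(long$track == "total_mean", "total", "unique")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$start, y = .data$depth,
                                     colour = .data$track)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position (bp)",
                  y = sprintf("mean depth (%d-bp window)", window),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a sliding-window identity track
#'
#' @param object An [window_identity_track()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot identity_track
#' @export
autoplot.identity_track <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$start, y = .data$identity)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::coord_cartesian(ylim = c(NA, 100)) +
    ggplot2::labs(x = "reference position (bp)", y = "% identity") +
    ggplot2::theme_minimal()
}

#' Plot a dot-plot identity matrix
#'
#' @param object A [dotplot_identity()] matrix.
#' @param min_identity Identity floor of the colour scale (cells below are
#'   blank), default 75.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dotplot_identity
#' @export
autoplot.dotplot_identity <- function(object, min_identity = 75, ...) {
  df <- expand.grid(a = as.integer(rownames(object)),
                    b = as.integer(colnames(object)))
  df$identity <- as.vector(object)
  df$identity[df$identity < min_identity] <- NA_real_
  ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$b,
                                   fill = .data$identity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "white",
                                  limits = c(min_identity, 100)) +
    ggplot2::labs(x = "sequence A (bp)", y = "sequence B (bp)",
                  fill = "% identity") +
    ggplot2::theme_minimal()
}

#' Plot a presence run: per-gene unique coverage against the control
#'
#' @param object A `presence_run` from [infer_presence()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot presence_run
#' @export
autoplot.presence_run <- function(object, ...) {
  calls <- object$calls
  df <- tidyr::pivot_longer(
    calls[, c("gene_id", "status", "unique_cov_pct", "control_cov_pct")],
    c("unique_cov_pct", "control_cov_pct"),
    names_to = "set", values_to = "pct")
  df$set <- ifelse(df$set == "unique_cov_pct", "sample", "control")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene_id, y = .data$pct,
                                   fill = .data$set)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_text(
      data = calls,
      ggplot2::aes(x = .data$gene_id, y = 102, label = .data$status),
      inherit.aes = FALSE, angle = 90, hjust = 0, size = 3) +
    ggplot2::coord_cartesian(ylim = c(0, 130)) +
    ggplot2::labs(x = NULL, y = "% unique coverage", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
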