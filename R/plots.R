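#' Plot an axial slice of a label map
#'
#' @param object A [label_map()] (or use [autoplot.subseg_result()] /
#'   `autoplot()` on a run).
#' @param slice Slice index along the third axis; defaults to the middle.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.label_map <- function(object, slice = NULL, ...) {
  d <- dim(object$labels)
  if (is.null(slice)) slice <- ceiling(d[3] / 2)
  sl <- object$labels[, , slice]
  df <- tidyr::expand_grid(x = seq_len(d[1]), y = seq_len(d[2]))
  df$code <- as.vector(sl)
  df$class <- factor(
    ifelse(df$code == 0L, "background", class_name(pmax(df$code, 1L))),
    levels = c("background", .classes)
  )
  pal <- c(background = "black", csf = "#3b4cc0", gm = "#999999",
           wm = "#f7f7f7", pallidum = "#d7191c", putamen = "#1a9641",
           thalamus = "#41b6c4", caudate = "#ffd92f")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = pal, drop = FALSE) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = paste0("Axial slice z = ", slice),
                  x = NULL, y = NULL, fill = "Class") +
    ggplot2::theme_void()
}

#' @rdname autoplot.label_map
#' @export
autoplot.subseg_result <- function(object, slice = NULL, ...) {
  autoplot.label_map(object$labels, slice = slice, ...)
}

#' @rdname autoplot.label_map
#' @export
autoplot.subseg_run <- function(object, slice = NULL, ...) {
  autoplot.label_map(object$result$labels, slice = slice, ...)
}

#' Bar chart of a per-class volume report
#'
#' @param report A [compute_volumes()] tibble (optionally several,
#'   row-bound with a distinguishing column passed as `fill`).
#' @param fill Optional column name used to fill/dodge bars.
#' @return A ggplot object.
#' @export
plot_volumes <- function(report, fill = NULL) {
  p <- ggplot2::ggplot(report,
                       ggplot2::aes(x = factor(.data$class, levels = .classes),
                                    y = .data$volume_cc))
  if (is.null(fill)) {
    p <- p + ggplot2::geom_col(fill = "steelblue")
  } else {
    p <- p + ggplot2::geom_col(ggplot2::aes(fill = .data[[fill]]),
                               position = "dodge")
  }
  p + ggplot2::labs(x = NULL, y = "Volume (cc)") +
    ggplot2::theme_minimal()
}
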