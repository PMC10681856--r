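#' @importFrom ggplot2 ggplot aes geom_tile geom_point geom_line geom_vline
#'   scale_fill_gradient2 labs theme_minimal theme element_text autoplot
#'   ggsave coord_fixed
NULL

#' @export
ggplot2::autoplot

#' Heatmap of an association matrix
#'
#' Diverging palette centered at 0 (so zeroed non-significant cells sit at
#' the palette midpoint), rows and columns in cluster order when the matrix
#' has been clustered.
#'
#' @param object An `association_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot association_matrix
#' @export
autoplot.association_matrix <- function(object, ...) {
  vals <- object$values
  ro <- if (is.null(object$row_order)) seq_len(nrow(vals)) else object$row_order
  co <- if (is.null(object$col_order)) seq_len(ncol(vals)) else object$col_order
  df <- tidy.association_matrix(object)
  df$rs1 <- factor(df$rs1, levels = rownames(vals)[ro])
  df$rs2 <- factor(df$rs2, levels = colnames(vals)[co])
  lim <- max(abs(df$value), 1e-9)
  ggplot(df, aes(x = .data$rs2, y = .data$rs1, fill = .data$value)) +
    geom_tile() +
    scale_fill_gradient2(low = "#2166AC", mid = "white", high = "#B2182B",
                         midpoint = 0, limits = c(-lim, lim),
                         name = object$stat) +
    labs(x = NULL, y = NULL) +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 90, hjust = 1, vjust = 0.5))
}

#' @rdname autoplot.association_matrix
#' @param m An `association_matrix`.
#' @export
plot_crosswise_matrix <- function(m, ...) autoplot.association_matrix(m, ...)

#' Scatter plot of a 2-D embedding
#'
#' @param embedding The tibble returned by [dim_red()].
#' @param label Draw region-set names next to the points.
#' @return A ggplot object.
#' @export
plot_dimred <- function(embedding, label = FALSE) {
  p <- ggplot(embedding, aes(x = .data$x, y = .data$y,
                             colour = .data$cluster)) +
    geom_point(size = 2) +
    labs(title = toupper(embedding$method[1]), x = "dim 1", y = "dim 2") +
    theme_minimal()
  if (label) {
    p <- p + ggplot2::geom_text(aes(label = .data$name), hjust = -0.15,
                                size = 2.7, show.legend = FALSE)
  }
  p
}

#' Heatmap of local Z-score profiles
#'
#' One row per target set (cluster order), one column per shift; a vertical
#' guide marks shift 0 so sharp, regional and flanking geometries are
#' immediately distinguishable.
#'
#' @param object A `local_z_matrix` (see [local_z_matrix()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot local_z_matrix
#' @export
autoplot.local_z_matrix <- function(object, ...) {
  m <- object$values
  df <- as_tibble(as.data.frame.table(m, responseName = "value",
                                      stringsAsFactors = FALSE))
  names(df)[1:2] <- c("target", "shift")
  df$shift <- as.numeric(df$shift)
  df$target <- factor(df$target, levels = rownames(m)[object$row_order])
  lim <- max(abs(df$value), 1e-9)
  ggplot(df, aes(x = .data$shift, y = .data$target, fill = .data$value)) +
    geom_tile() +
    geom_vline(xintercept = 0, linetype = 2, linewidth = 0.3) +
    scale_fill_gradient2(low = "#2166AC", mid = "white", high = "#B2182B",
                         midpoint = 0, limits = c(-lim, lim),
                         name = object$stat) +
    labs(x = "shift (bp)", y = NULL,
         title = paste0("Local Z-score profiles of ", object$focal_name)) +
    theme_minimal()
}

#' @rdname autoplot.local_z_matrix
#' @param lzm A `local_z_matrix`.
#' @export
plot_local_z <- function(lzm, ...) autoplot.local_z_matrix(lzm, ...)

#' Line plot of the profiles of a local Z-score result
#'
#' @param object A `local_z_result`.
#' @param stat `"norm_zscore"` or `"zscore"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot local_z_result
#' @export
autoplot.local_z_result <- function(object, stat = "norm_zscore", ...) {
  df <- object$profiles
  ggplot(df, aes(x = .data$shift, y = .data[[stat]],
                 colour = .data$target)) +
    geom_line() +
    geom_vline(xintercept = 0, linetype = 2, linewidth = 0.3) +
    labs(x = "shift (bp)", y = stat,
         title = paste0("Local association profiles of ",
                        object$focal_name)) +
    theme_minimal()
}
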