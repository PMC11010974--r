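# Plot helpers (ggplot2, Suggests). t-SNE plots omit axis labels: the
# embedding plane is unitless and only locally interpretable.

need_ggplot2 <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop_hspc("ggplot2 is required for plotting", "hspcmap_plot_error")
  }
}

#' Density plot of an embedding subset
#'
#' Renders a density picture normalized to its own maximum, optionally with
#' gate polygons overlaid.
#'
#' @param picture density matrix from [density_matrix()].
#' @param grid the matching [density_grid()].
#' @param gate_set optional [tsne_gate_set()] overlay.
#' @param title plot title.
#' @return a ggplot object.
#' @export
plot_density_picture <- function(picture, grid, gate_set = NULL,
                                 title = NULL) {
  need_ggplot2()
  nb <- grid$n_bins
  xc <- (grid$xbreaks[-1] + grid$xbreaks[-(nb + 1)]) / 2
  yc <- (grid$ybreaks[-1] + grid$ybreaks[-(nb + 1)]) / 2
  df <- expand.grid(x = xc, y = yc)
  df$density <- as.vector(picture) / max(picture)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = x, y = y,
                                        fill = density)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.title = ggplot2::element_blank(),
                   axis.text = ggplot2::element_blank()) +
    ggplot2::ggtitle(title)
  if (!is.null(gate_set)) {
    for (g in gate_set$gates) {
      poly <- as.data.frame(g$vertices)
      names(poly) <- c("x", "y")
      p <- p + ggplot2::geom_polygon(
        data = poly, ggplot2::aes(x = x, y = y),
        inherit.aes = FALSE, fill = NA, color = "white", linewidth = 0.3)
    }
  }
  p
}

#' Marker box plots per gate and group
#'
#' @param matrix embedded expression matrix.
#' @param membership gate labels from [assign_gate_membership()].
#' @param gates gate names to display (default: all non-ungated).
#' @return a ggplot object.
#' @export
plot_gate_boxplots <- function(matrix, membership, gates = NULL) {
  need_ggplot2()
  if (is.null(gates)) gates <- setdiff(unique(membership), "ungated")
  keep <- membership %in% gates
  long <- do.call(rbind, lapply(hspc_markers(), function(m) {
    data.frame(gate = membership[keep], group = matrix$group[keep],
               marker = m, value = matrix[[m]][keep])
  }))
  ggplot2::ggplot(long, ggplot2::aes(x = marker, y = value,
                                     fill = group)) +
    ggplot2::geom_boxplot(outlier.size = 0.3) +
    ggplot2::facet_wrap(~gate) +
    ggplot2::labs(y = "scaled intensity", x = NULL) +
    ggplot2::theme_minimal()
}
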