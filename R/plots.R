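SS_COLOURS <- c(H = "#D81B60", G = "#F06292", I = "#F8BBD0",
                E = "#FFC107", B = "#FFE082",
                T = "#1E88E5", S = "#90CAF9", C = "grey85")

#' Plot a secondary-structure timeline
#'
#' Frame-by-residue tile plot of Kabsch-Sander codes, the standard way of
#' looking at helix/coil evolution along a trajectory.
#'
#' @param object A `pep_sstimeline` from [ss_timeline()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pep_sstimeline <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frame, y = .data$resno,
                                   fill = .data$code)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = SS_COLOURS, name = "DSSP") +
    ggplot2::scale_y_continuous(breaks = unique(df$resno)) +
    ggplot2::labs(x = "frame", y = "residue") +
    ggplot2::theme_minimal()
}

#' Plot a free-energy surface
#'
#' @param object A `pep_fes` from [fes2d()]. Empty (masked) bins are drawn
#'   blank.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pep_fes <- function(object, ...) {
  df <- object$grid[object$grid$occupied, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x_center, y = .data$y_center,
                                   fill = .data$dG)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = expression(Delta * G ~ "(kcal/mol)"),
                                  direction = -1) +
    ggplot2::coord_cartesian(xlim = c(-180, 180), ylim = c(-180, 180)) +
    ggplot2::labs(x = object$axis_labels[1], y = object$axis_labels[2]) +
    ggplot2::theme_minimal()
}

#' Plot dPCA projections coloured by cluster
#'
#' @param object A `pep_dpca` from [dpca()].
#' @param ... Unused.
#' @return A ggplot object (first two components; unassigned frames grey).
#' @export
autoplot.pep_dpca <- function(object, ...) {
  df <- tidy(object)
  df$cluster <- factor(df$cluster)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                   colour = .data$cluster)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.5) +
    ggplot2::scale_colour_manual(
      values = c("0" = "grey70",
                 setNames(scales_hue(length(object$occupancies)),
                          seq_along(object$occupancies)))) +
    ggplot2::labs(x = "PC1", y = "PC2", colour = "cluster") +
    ggplot2::theme_minimal()
}

scales_hue <- function(n) {
  grDevices::hcl(h = seq(15, 375, length.out = n + 1)[seq_len(n)],
                 l = 65, c = 100)
}
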