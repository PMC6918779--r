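#' Plot the tissue as filled cell polygons
#'
#' @param object a `vm_mesh`.
#' @param fill one of `"area"`, `"domain"`, `"clone"`, `"sides"`, `"none"`.
#' @param state optional per-cell state (for `"domain"`/`"clone"` fills).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.vm_mesh <- function(object, fill = "area", state = NULL, ...) {
  nc <- n_cells(object)
  polys <- lapply(seq_len(nc), function(a) {
    p <- cell_polygon(object, a)
    tibble::tibble(cell = a, x = p[, 1], y = p[, 2])
  })
  d <- dplyr::bind_rows(polys)
  fills <- switch(fill,
    area = vapply(seq_len(nc), function(a) cell_area(object, a), 0),
    sides = as.factor(cell_sides(object)),
    domain = if (!is.null(state)) as.factor(state$domain) else factor(rep("pD", nc)),
    clone = if (!is.null(state)) as.factor(state$clone) else factor(seq_len(nc)),
    none = NULL
  )
  if (!is.null(fills)) d$fill <- fills[d$cell]
  gg <- ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y, group = .data$cell)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "DV (nondim.)", y = "AP (nondim.)") +
    ggplot2::theme_minimal()
  if (is.null(fills)) {
    gg + ggplot2::geom_polygon(fill = NA, colour = "grey30", linewidth = 0.2)
  } else {
    gg + ggplot2::geom_polygon(ggplot2::aes(fill = .data$fill),
                               colour = "grey30", linewidth = 0.2) +
      ggplot2::labs(fill = fill)
  }
}

#' @rdname autoplot.vm_mesh
#' @export
autoplot.vm_sim <- function(object, fill = "domain", ...) {
  autoplot.vm_mesh(object$mesh, fill = fill, state = object$state, ...) +
    ggplot2::ggtitle(sprintf("t = %.1f h, %d cells, AP/DV = %.2f",
                             object$t_hours, n_cells(object$mesh),
                             tissue_aspect_ratio(object$mesh)))
}

#' Histograms of the four cell-geometry descriptors
#'
#' @param object a `vm_geometry_table`.
#' @param ... unused.
#' @return a ggplot with facets for area, perimeter, neighbour number and
#'   elongation.
#' @export
autoplot.vm_geometry_table <- function(object, ...) {
  d <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object), "area", "perimeter",
                  "n_neighbours", "elongation"),
    dplyr::everything(), names_to = "feature", values_to = "value"
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$value)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue", colour = "white") +
    ggplot2::facet_wrap(~feature, scales = "free") +
    ggplot2::theme_minimal()
}

#' Parameter-screen heatmap
#'
#' @param object a `vm_screen` tibble.
#' @param score which score column to map to colour.
#' @param ... unused.
#' @return a ggplot tile map over `(lambda_bar, gamma_bar)`.
#' @export
autoplot.vm_screen <- function(object, score = "geometry_score", ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$lambda_bar, .data$gamma_bar,
                                       fill = .data[[score]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(direction = -1) +
    ggplot2::labs(x = expression(bar(Lambda)), y = expression(bar(Gamma))) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.vm_lewis_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(.data$n_neighbours, .data$rel_area)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n)) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "firebrick") +
    ggplot2::labs(x = "neighbour number", y = "relative mean area") +
    ggplot2::theme_minimal()
}
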