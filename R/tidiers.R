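#' Tidy a simulation into its per-cell geometry table
#'
#' @param x a `vm_sim` object.
#' @param ... unused.
#' @return a `vm_geometry_table` tibble (one row per surviving cell).
#' @export
tidy.vm_sim <- function(x, ...) geometry_table(x$mesh, x$state)

#' One-row summary of a simulation
#'
#' @param x a `vm_sim` object.
#' @param ... unused.
#' @return a one-row tibble: cell count, tracked time, box lengths, AP/DV
#'   aspect ratio, mean apical area and event totals.
#' @export
glance.vm_sim <- function(x, ...) {
  fr <- vertex_forces(x$mesh, x$config$mech, rep(1, n_cells(x$mesh)))
  tibble::tibble(
    n_cells = n_cells(x$mesh), t_hours = x$t_hours,
    L_DV = x$mesh$box[1], L_AP = x$mesh$box[2],
    aspect_ratio = tissue_aspect_ratio(x$mesh),
    mean_area = mean(fr$area), mean_sides = mean(cell_sides(x$mesh)),
    n_divisions = nrow(x$events$divisions), n_t1 = nrow(x$events$t1),
    n_extrusions = nrow(x$events$extrusions)
  )
}

#' @export
tidy.vm_lewis_fit <- function(x, ...) {
  s <- suppressWarnings(summary(x$model))$coefficients
  tibble::tibble(term = rownames(s), estimate = as.numeric(s[, 1]),
                 std.error = as.numeric(s[, 2]),
                 statistic = as.numeric(s[, 3]),
                 p.value = as.numeric(s[, 4]))
}

#' @export
glance.vm_lewis_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, slope = x$slope,
                 intercept = x$intercept, n_classes = nrow(x$data))
}

#' @export
print.vm_lewis_fit <- function(x, ...) {
  cat(sprintf("Lewis-law fit: rel_area = %.3f + %.3f * n, R^2 = %.3f (%d classes)\n",
              x$intercept, x$slope, x$r_squared, nrow(x$data)))
  invisible(x)
}
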