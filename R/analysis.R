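#' Second-moment shape descriptors of a polygon
#'
#' Elongation is the square root of the ratio of the largest to smallest
#' eigenvalue of the second-moment matrix of the vertex coordinates about
#' their centroid; 1 for shapes with a fourfold-or-higher symmetry (regular
#' hexagon, square), 2 for a 2x1 rectangle.
#'
#' @param poly `n x 2` matrix of vertex coordinates (already unwrapped; use
#'   [cell_polygon()] for mesh cells).
#' @return elongation `>= 1`.
#' @export
cell_elongation <- function(poly) {
  if (nrow(poly) < 3) stop("polygon needs at least 3 vertices")
  m <- second_moment(poly)
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (ev[2] <= .Machine$double.eps * max(1, ev[1])) {
    stop("degenerate (collinear) polygon")
  }
  sqrt(ev[1] / ev[2])
}

second_moment <- function(poly) {
  cen <- colMeans(poly)
  d <- sweep(poly, 2, cen)
  crossprod(d) / nrow(poly)
}

#' Orientation of the long axis relative to the DV axis
#'
#' The angle `arctan(x1 / y1)` where `x1`, `y1` are the AP and DV components
#' of the leading eigenvector of the second-moment matrix: 0 means the long
#' axis points along DV, `pi/2` along AP. Isotropic cells (equal
#' eigenvalues within `tol`) have no major axis and return `NA` (excluded
#' from angle histograms).
#'
#' @param poly polygon vertex matrix.
#' @param tol relative eigenvalue gap below which the cell is isotropic.
#' @return angle in `(-pi/2, pi/2]`, or `NA` for isotropic cells.
#' @export
cell_orientation_angle <- function(poly, tol = 1e-9) {
  m <- second_moment(poly)
  e <- eigen(m, symmetric = TRUE)
  if ((e$values[1] - e$values[2]) <= tol * max(e$values[1], .Machine$double.eps)) {
    return(NA_real_)
  }
  v <- e$vectors[, 1]
  ang <- atan2(v[2], v[1])            # v = (DV, AP) components
  ang <- atan(tan(ang))               # fold to (-pi/2, pi/2)
  if (ang == -pi / 2) ang <- pi / 2
  ang
}

#' DV length of a cell
#'
#' Extent of the (unwrapped) vertex x-coordinates, `max(x) - min(x)`; the
#' x-axis is the DV direction.
#'
#' @param poly polygon vertex matrix.
#' @return non-negative length.
#' @export
cell_dv_length <- function(poly) max(poly[, 1]) - min(poly[, 1])

#' Per-cell geometry table
#'
#' The segmented-image-style descriptor table: one row per cell with apical
#' area, perimeter, neighbour (side) count, elongation, orientation angle,
#' DV length, centroid and, when per-cell state is available, clone, domain
#' and differentiation flag. This is the common currency between simulation
#' snapshots and (synthetic or experimental) segmentation tables.
#'
#' @param mesh a `vm_mesh`.
#' @param state optional per-cell state (the internal engine state or the
#'   `state` tibble of a `vm_sim`).
#' @return a `vm_geometry_table` tibble with attributes `units`
#'   (`"nondim"`) and `provenance` (`"simulation"`).
#' @export
geometry_table <- function(mesh, state = NULL) {
  nc <- n_cells(mesh)
  area <- perim <- elong <- orient <- dvl <- cx <- cy <- numeric(nc)
  for (a in seq_len(nc)) {
    p <- cell_polygon(mesh, a)
    n <- nrow(p)
    k1 <- c(2:n, 1)
    cr <- p[, 1] * p[k1, 2] - p[k1, 1] * p[, 2]
    area[a] <- 0.5 * sum(cr)
    perim[a] <- sum(sqrt((p[k1, 1] - p[, 1])^2 + (p[k1, 2] - p[, 2])^2))
    elong[a] <- tryCatch(cell_elongation(p), error = function(e) NA_real_)
    orient[a] <- if (is.na(elong[a]) || elong[a] <= 1 + 1e-9) NA_real_ else
      cell_orientation_angle(p)
    dvl[a] <- cell_dv_length(p)
    cen <- c(sum((p[, 1] + p[k1, 1]) * cr), sum((p[, 2] + p[k1, 2]) * cr)) /
      (6 * area[a])
    cx[a] <- cen[1] %% mesh$box[1]; cy[a] <- cen[2] %% mesh$box[2]
  }
  tbl <- tibble::tibble(
    cell = seq_len(nc), area = area, perimeter = perim,
    n_neighbours = cell_sides(mesh), elongation = elong,
    orientation_angle = orient, dv_length = dvl,
    centroid_x = cx, centroid_y = cy
  )
  if (!is.null(state)) {
    doms <- c("pD", "pMN")
    if (is.list(state) && !is.data.frame(state)) {
      tbl$clone <- state$clone
      tbl$domain <- doms[state$dom]
      tbl$differentiating <- state$diff
    } else {
      tbl$clone <- state$clone
      tbl$domain <- state$domain
      tbl$differentiating <- state$differentiating
    }
  }
  structure(tbl, units = "nondim", provenance = "simulation",
            class = c("vm_geometry_table", class(tbl)))
}

# pointwise-mean ECDF of one or several samples, evaluated at `grid`
mean_ecdf <- function(samples, grid) {
  if (!is.list(samples)) samples <- list(samples)
  fs <- vapply(samples, function(s) stats::ecdf(s)(grid), numeric(length(grid)))
  rowMeans(fs)
}

#' Kolmogorov-Smirnov distance between (mean) empirical distributions
#'
#' `D = sup |ECDF_a - ECDF_b|`. Either side may be a single sample or a list
#' of replicate samples; replicate ECDFs are averaged pointwise on the merged
#' support grid before the supremum is taken (comparison of mean
#' distributions, as used for the parameter screen).
#'
#' @param a,b numeric vectors, or lists of numeric vectors (replicates).
#' @return `D` in `[0, 1]`.
#' @export
ks_statistic <- function(a, b) {
  va <- unlist(a, use.names = FALSE)
  vb <- unlist(b, use.names = FALSE)
  if (!length(va) || !length(vb)) stop("empty sample")
  grid <- sort(unique(c(va, vb)))
  max(abs(mean_ecdf(a, grid) - mean_ecdf(b, grid)))
}

table_units <- function(tbl) attr(tbl, "units") %||% "nondim"

#' Geometry similarity score (parameter screen, distribution match)
#'
#' The mean of five components comparing simulated and reference cell
#' geometry: K-S distances of the mean ECDFs of cell area, cell perimeter
#' and neighbour number, plus the absolute differences of the standard
#' deviations of area and of perimeter (reference mean s.d. vs each
#' simulated replicate, averaged over replicates). Lower is better; a table
#' compared with itself scores 0.
#'
#' @param sim one `vm_geometry_table` or a list of replicate tables.
#' @param ref one reference table or a list (e.g. per-image tables).
#' @param area_scale area unit of the reference expressed in simulation
#'   units (e.g. 23 when the reference is in um^2 and the simulation is
#'   nondimensional with a 23 um^2 unit). Required when the units differ.
#' @return scalar score, with per-component breakdown in attribute
#'   `components`.
#' @export
geometry_similarity_score <- function(sim, ref, area_scale = NULL) {
  as_list <- function(x) if (inherits(x, "data.frame")) list(x) else x
  sim <- as_list(sim); ref <- as_list(ref)
  us <- unique(vapply(sim, table_units, ""))
  ur <- unique(vapply(ref, table_units, ""))
  if (length(us) != 1 || length(ur) != 1) stop("mixed units within one side")
  if (us != ur) {
    if (is.null(area_scale)) {
      stop("unit mismatch (", us, " vs ", ur, "): supply area_scale")
    }
    ref <- lapply(ref, function(tb) {
      tb$area <- tb$area / area_scale
      tb$perimeter <- tb$perimeter / sqrt(area_scale)
      tb
    })
  }
  col <- function(tabs, nm) lapply(tabs, function(tb) tb[[nm]])
  sd_ref_area <- mean(vapply(ref, function(tb) stats::sd(tb$area), 0))
  sd_ref_per <- mean(vapply(ref, function(tb) stats::sd(tb$perimeter), 0))
  comp <- c(
    ks_area = ks_statistic(col(sim, "area"), col(ref, "area")),
    ks_perimeter = ks_statistic(col(sim, "perimeter"), col(ref, "perimeter")),
    ks_neighbours = ks_statistic(col(sim, "n_neighbours"), col(ref, "n_neighbours")),
    d_sd_area = mean(vapply(sim, function(tb) abs(sd_ref_area - stats::sd(tb$area)), 0)),
    d_sd_perimeter = mean(vapply(sim, function(tb) abs(sd_ref_per - stats::sd(tb$perimeter)), 0))
  )
  structure(mean(comp), components = comp)
}

#' Tissue-scale fit score (parameter screen, growth match)
#'
#' Per simulation run: `|log(dDV_sim) - log(dDV_ref)| + |ratio_sim -
#' ratio_ref|`, where `dDV` is the change in tissue DV length over the
#' tracked window and `ratio` the final AP/DV aspect ratio; averaged over
#' runs.
#'
#' @param dv_change_sim,final_ratio_sim per-run vectors.
#' @param dv_change_ref,final_ratio_ref reference scalars.
#' @return scalar score.
#' @export
tissue_fit_score <- function(dv_change_sim, final_ratio_sim,
                             dv_change_ref, final_ratio_ref) {
  if (any(dv_change_sim <= 0) || dv_change_ref <= 0) {
    stop("DV length change must be positive for the log-scale comparison")
  }
  mean(abs(log(dv_change_sim) - log(dv_change_ref)) +
         abs(final_ratio_sim - final_ratio_ref))
}

#' Clone AP/DV spread ratio
#'
#' `(mean AP extent - 1) / (mean DV extent - 1)`: one nondimensional length
#' unit (one cell diameter) is subtracted from each mean extent so that
#' single-cell clones contribute zero spread.
#'
#' @param clones a clone record tibble ([track_clones()] output).
#' @return scalar ratio.
#' @export
clone_spread_ratio <- function(clones) {
  if (!nrow(clones)) stop("no clones")
  m_ap <- mean(clones$ap_extent)
  m_dv <- mean(clones$dv_extent)
  if (m_ap <= 1 || m_dv <= 1) {
    stop("clones too small for corrected ratio (mean extent <= 1 unit)")
  }
  (m_ap - 1) / (m_dv - 1)
}

#' Proliferation rate estimator
#'
#' `lambda = d / (N_mean * dt)`: division events per cell per unit time.
#' For a proliferating tissue without differentiation, `lambda =
#' ln(2) / t_T`.
#'
#' @param d number of division events in the window.
#' @param n_mean mean cell count during the window.
#' @param dt_hours window length in hours.
#' @return rate per hour.
#' @export
proliferation_rate <- function(d, n_mean, dt_hours) {
  stopifnot(n_mean > 0, dt_hours > 0)
  d / (n_mean * dt_hours)
}

#' Effective tissue growth rate
#'
#' `k = ln(N_end / N_start) / dt`; equals the proliferation rate in the
#' absence of differentiation.
#'
#' @param n_start,n_end cell counts at the window ends.
#' @param dt_hours window length in hours.
#' @return rate per hour.
#' @export
effective_growth_rate <- function(n_start, n_end, dt_hours) {
  stopifnot(n_start > 0, n_end > 0, dt_hours > 0)
  log(n_end / n_start) / dt_hours
}

#' Fold an angle to `[0, pi/2]` relative to the DV axis
#' @param angle angle(s) in radians.
#' @return folded angle: 0 = DV-aligned, pi/2 = AP-aligned.
#' @export
fold_angle <- function(angle) {
  a <- abs(angle) %% pi
  ifelse(a > pi / 2, pi - a, a)
}

#' T1 transition statistics
#'
#' Rate of T1 events per cell per hour over a trailing window, plus the
#' folded orientation angles of the newly formed edges.
#'
#' @param t1_events the `t1` tibble of a `vm_sim` event log.
#' @param window_hours length of the measurement window.
#' @param n_bar mean cell count during the window.
#' @param t_end end of the window in simulation hours (default: last event).
#' @return list with `rate` (per cell per hour), `angles` (folded new-edge
#'   angles in the window) and `n_events`.
#' @export
t1_statistics <- function(t1_events, window_hours, n_bar, t_end = NULL) {
  if (!nrow(t1_events)) {
    return(list(rate = 0, angles = numeric(0), n_events = 0L))
  }
  t_end <- t_end %||% max(t1_events$t_hours)
  sel <- t1_events$t_hours > t_end - window_hours & t1_events$t_hours <= t_end
  list(rate = sum(sel) / (n_bar * window_hours),
       angles = fold_angle(t1_events$angle_new[sel]),
       n_events = sum(sel))
}

#' Division-orientation distribution and uniformity test
#'
#' The division axis is perpendicular to the newly formed daughter
#' interface; axes are folded to `[0, pi/2]` relative to DV and tested for
#' uniformity with a Kolmogorov-Smirnov statistic.
#'
#' @param div_events the `divisions` tibble of a `vm_sim` event log.
#' @return list with `angles` (folded division-axis angles), `statistic` and
#'   `p_value` of the uniformity test.
#' @export
division_angle_distribution <- function(div_events) {
  if (!nrow(div_events)) stop("no division events")
  axis <- fold_angle(div_events$new_edge_angle + pi / 2)
  kt <- suppressWarnings(stats::ks.test(axis, stats::punif, 0, pi / 2))
  list(angles = axis, statistic = unname(kt$statistic), p_value = kt$p.value)
}

#' Lewis's-law fit
#'
#' Linear fit of the relative mean cell area (class mean divided by the
#' overall mean) against neighbour number; epithelial tilings obey an
#' approximately linear, increasing relation.
#'
#' @param table a `vm_geometry_table`.
#' @param min_class_size smallest neighbour class included.
#' @return a `vm_lewis_fit` with `slope`, `intercept`, `r_squared`, the
#'   class-mean `data` and the underlying `lm`.
#' @export
lewis_law_fit <- function(table, min_class_size = 3) {
  d <- dplyr::summarise(dplyr::group_by(tibble::as_tibble(table), n_neighbours),
                        rel_area = mean(area) / mean(table$area),
                        n = dplyr::n(), .groups = "drop")
  d <- dplyr::filter(d, n >= min_class_size)
  if (nrow(d) < 3) stop("need at least 3 neighbour classes for a fit")
  fit <- stats::lm(rel_area ~ n_neighbours, data = d)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = suppressWarnings(summary(fit))$r.squared,
                 data = d, model = fit),
            class = "vm_lewis_fit")
}

#' Asymptotic AP/DV aspect-ratio bounds under anisotropic drag
#'
#' In the rapid-growth limit the tissue aspect ratio approaches the square
#' root of the drag-coefficient ratio; in the slow-growth limit it stays
#' near one. Observed ratios should lie between the two.
#'
#' @param mu_dv,mu_ap drag coefficients.
#' @return named vector `c(fast = sqrt(mu_dv/mu_ap), slow = 1)`.
#' @export
aspect_ratio_bounds <- function(mu_dv, mu_ap) {
  stopifnot(mu_dv > 0, mu_ap > 0)
  c(fast = sqrt(mu_dv / mu_ap), slow = 1)
}

#' Synthetic segmented-image geometry table
#'
#' Generates a geometry table emulating an embryonic-neuroepithelium
#' segmentation: unimodal (gamma) area distribution at the requested
#' moments, perimeters tied to area through the hexagon isoperimetric ratio
#' with mild lognormal scatter, integer neighbour counts symmetric about 6
#' (discretised normal on 3..9), and elongations >= 1. This is a synthetic
#' stand-in for experimental image tables, used to exercise the screening
#' machinery; it does not model spatial correlations between neighbouring
#' cells.
#'
#' @param n_cells number of rows.
#' @param mean_area,sd_area area moments (default 23 and 8 um^2).
#' @param neighbour_sd spread of the neighbour-count distribution.
#' @param seed integer seed for reproducibility.
#' @return a `vm_geometry_table` with `units = "um2"` and
#'   `provenance = "synthetic"`.
#' @export
synthetic_geometry_fixture <- function(n_cells, mean_area = 23, sd_area = 8,
                                       neighbour_sd = 1.5, seed = NULL) {
  stopifnot(n_cells > 0, mean_area > 0, sd_area >= 0, neighbour_sd >= 0)
  if (sd_area >= mean_area) stop("infeasible moments: sd_area must be < mean_area")
  if (!is.null(seed)) set.seed(seed)
  shape <- (mean_area / max(sd_area, 1e-9))^2
  area <- stats::rgamma(n_cells, shape = shape, scale = mean_area / shape)
  p_hex <- 6 / sqrt(3 * sqrt(3) / 2)
  perimeter <- p_hex * sqrt(area) * stats::rlnorm(n_cells, 0, 0.04)
  kk <- 3:9
  pr <- stats::dnorm(kk, 6, max(neighbour_sd, 1e-9))
  nb <- sample(kk, n_cells, replace = TRUE, prob = pr)
  elong <- 1 + stats::rgamma(n_cells, shape = 2, scale = 0.12)
  orient <- stats::runif(n_cells, -pi / 2, pi / 2)
  tbl <- tibble::tibble(
    cell = seq_len(n_cells), area = area, perimeter = perimeter,
    n_neighbours = nb, elongation = elong, orientation_angle = orient,
    dv_length = sqrt(area) * stats::rlnorm(n_cells, 0, 0.1),
    centroid_x = stats::runif(n_cells, 0, 80),
    centroid_y = stats::runif(n_cells, 0, 80)
  )
  structure(tbl, units = "um2", provenance = "synthetic",
            class = c("vm_geometry_table", class(tbl)))
}
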