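#' Time-unit conversions
#'
#' The nondimensional unit system uses 460 s as the unit of time and
#' 23 um^2 as the unit of area.
#'
#' @param h hours.
#' @return time in nondimensional units.
#' @export
hours_to_units <- function(h) h * 3600 / 460

#' @rdname hours_to_units
#' @param u nondimensional time.
#' @export
units_to_hours <- function(u) u * 460 / 3600

#' Cell cycle phase durations
#'
#' Phase durations as fixed proportions of the total cycle `t_T`: G1, the
#' S+G2 aggregate (of which S is 1/3 and G2 is 2/3) and M. Defaults follow
#' the dorsal neural-tube cycle: 13 h total, 55% G1, 40% S+G2, 5% M.
#'
#' @param t_T_hours total cell cycle length in hours.
#' @param p_G1,p_SG2,p_M phase proportions (must sum to 1).
#' @return a `vm_phases` list with `t_G1`, `t_S`, `t_G2`, `t_M`, `t_T` in
#'   nondimensional time units, plus `t_T_hours`.
#' @export
cell_cycle_phases <- function(t_T_hours = 13, p_G1 = 0.55, p_SG2 = 0.40,
                              p_M = 0.05) {
  stopifnot(abs(p_G1 + p_SG2 + p_M - 1) < 1e-9, t_T_hours > 0,
            p_G1 >= 0, p_SG2 >= 0, p_M >= 0)
  t_T <- hours_to_units(t_T_hours)
  structure(list(t_G1 = p_G1 * t_T, t_S = p_SG2 * t_T / 3,
                 t_G2 = 2 * p_SG2 * t_T / 3, t_M = p_M * t_T,
                 t_T = t_T, t_T_hours = t_T_hours),
            class = "vm_phases")
}

#' Apicobasal nuclear position over the cell cycle
#'
#' Piece-wise linear interkinetic nuclear movement: the nucleus (apical = 1,
#' basal = 0) descends linearly through G1, stays basal through S, ascends
#' linearly through G2 and is apical in M and beyond (cells that have not yet
#' met the division criterion wait apically).
#'
#' @param t_tilde age of the cell (time since birth, nondimensional), >= 0;
#'   vectorised.
#' @param phases a [cell_cycle_phases()] object.
#' @return `rho` in `[0, 1]`, continuous at the phase boundaries.
#' @export
apicobasal_position <- function(t_tilde, phases) {
  if (any(t_tilde < 0)) stop("cell age t_tilde must be non-negative")
  b1 <- phases$t_G1
  b2 <- b1 + phases$t_S
  b3 <- b2 + phases$t_G2
  rho <- rep(1, length(t_tilde))
  g1 <- t_tilde < b1
  rho[g1] <- 1 - t_tilde[g1] / b1
  s <- t_tilde >= b1 & t_tilde < b2
  rho[s] <- 0
  g2 <- t_tilde >= b2 & t_tilde < b3
  rho[g2] <- (t_tilde[g2] - b2) / phases$t_G2
  rho
}

#' Basal-to-apical interpolant of the target area
#'
#' Monotone convex map with `f(0) = 1/2` (basal) and `f(1) = 1` (apical),
#' rising faster as the nucleus approaches the apical surface.
#'
#' @param rho apicobasal position in `[0, 1]`.
#' @return interpolation factor in `[1/2, 1]`.
#' @export
apical_interpolant <- function(rho) (1 + rho^2) / 2

#' Time-dependent target area
#'
#' `A0(t) = (1 + g t_tilde) * f(rho(t_tilde))`: the product of linear volume
#' growth over the cycle and the apicobasal interpolation factor, so a cell
#' is born with unit apical target, shrinks its target as the nucleus moves
#' basally, and approaches twice the birth target when apical again at
#' mitosis (for `g = 1/t_T`). Differentiating cells are handled upstream by
#' setting the target to zero.
#'
#' @param t_tilde cell age (vectorised).
#' @param g per-cell growth rate (nondimensional, recycled).
#' @param phases a [cell_cycle_phases()] object.
#' @param interp interpolant, default [apical_interpolant()].
#' @return target areas.
#' @export
target_area <- function(t_tilde, g, phases, interp = apical_interpolant) {
  (1 + g * t_tilde) * interp(apicobasal_position(t_tilde, phases))
}

#' Sample per-cell growth rates
#'
#' Normal draws with mean `1/t_T` (the inverse cell life span; 1/780 min for
#' the 13 h cycle) and standard deviation 20% of the mean, redrawn while
#' non-positive.
#'
#' @param n number of draws.
#' @param phases a [cell_cycle_phases()] object (sets the mean).
#' @param sd_frac spread as a fraction of the mean.
#' @return positive growth rates, per nondimensional time.
#' @export
sample_growth_rate <- function(n, phases = cell_cycle_phases(), sd_frac = 0.2) {
  m <- 1 / phases$t_T
  g <- stats::rnorm(n, m, sd_frac * m)
  while (any(bad <- g <= 0)) {
    g[bad] <- stats::rnorm(sum(bad), m, sd_frac * m)
  }
  g
}

#' Division rule
#' @param A_c critical apical area for division (nondimensional), > 0.
#' @return a `vm_division_rule` list.
#' @export
division_rule <- function(A_c = 1.5) {
  stopifnot(A_c > 0)
  structure(list(A_c = A_c), class = "vm_division_rule")
}

#' Is a cell ready to divide?
#'
#' Division requires the cell to be in M phase (`t_tilde > t_G1 + t_S +
#' t_G2`), its area to exceed the critical value `A_c`, and the cell not to
#' be committed to differentiation. Cells past `t_T` that have not reached
#' `A_c` simply wait in M and keep growing.
#'
#' @param t_tilde cell ages (vectorised).
#' @param area current apical areas.
#' @param phases a [cell_cycle_phases()] object.
#' @param rule a [division_rule()] object.
#' @param differentiating logical flags.
#' @return logical vector.
#' @export
division_ready <- function(t_tilde, area, phases, rule = division_rule(),
                           differentiating = FALSE) {
  t_tilde > (phases$t_G1 + phases$t_S + phases$t_G2) &
    area > rule$A_c & !differentiating
}

#' Stochastic differentiation marking
#'
#' Each eligible cell (inside the mask and not already committed) commits to
#' neuronal differentiation with first-order hazard `rate * dt`; committed
#' cells have their target area set to zero thereafter and shrink towards
#' extrusion.
#'
#' @param differentiating current logical flags.
#' @param eligible logical mask of cells exposed to the hazard.
#' @param rate_per_hour differentiation rate (e.g. 0.1 for the pMN domain).
#' @param dt time step in nondimensional units.
#' @return updated logical flags.
#' @export
mark_differentiating <- function(differentiating, eligible, rate_per_hour, dt) {
  stopifnot(rate_per_hour >= 0)
  p <- rate_per_hour * units_to_hours(dt)
  if (p > 0.1) {
    warning("rate * dt > 0.1: first-order hazard approximation is degraded")
  }
  idx <- which(eligible & !differentiating)
  if (length(idx) && p > 0) {
    differentiating[idx] <- stats::runif(length(idx)) < p
  }
  differentiating
}
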