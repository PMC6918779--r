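#' Mechanical parameters of the vertex model
#'
#' The energy of the tissue is
#' \deqn{E = \sum_\alpha \frac{K}{2}(A_\alpha - A^0_\alpha(t))^2
#'   + \sum_{\langle ij\rangle} \Lambda\, l_{ij}
#'   + \sum_\alpha \frac{\Gamma}{2} L_\alpha^2,}
#' with uniform area elasticity `K`, junction tension `Lambda` and perimeter
#' contractility `Gamma` (for `Gamma != 0` the implied target perimeter is
#' `-Lambda / (2 Gamma)`). Vertices move by overdamped gradient descent
#' `mu dr_i/dt = F_i = -dE/dr_i`, integrated with the explicit Euler method.
#'
#' @param K area elasticity (> 0). The nondimensional unit system fixes K = 1.
#' @param Lambda junction tension (sign free; negative favours edge growth).
#' @param Gamma perimeter contractility (>= 0 in normal use).
#' @param mu vertex drag coefficient (> 0); 1 in nondimensional units.
#' @param dt Euler step in nondimensional time (1 unit = 460 s). The default
#'   1.017e-3 corresponds to 1e5 steps per 13 h cell cycle; production
#'   protocols may use a larger step after checking insensitivity.
#' @return a `vm_mech_params` list.
#' @export
mechanical_params <- function(K = 1, Lambda = 0, Gamma = 0, mu = 1,
                              dt = 1.017e-3) {
  stopifnot(K > 0, mu > 0, dt > 0)
  p <- list(K = K, Lambda = Lambda, Gamma = Gamma, mu = mu, dt = dt)
  p$L0 <- if (Gamma != 0) -Lambda / (2 * Gamma) else NA_real_
  structure(p, class = "vm_mech_params")
}

#' Dimensionless tension and contractility
#'
#' `lambda_bar = Lambda / (K A0^(3/2))` and `gamma_bar = Gamma / (K A0)`,
#' where `A0` is the cycle-averaged target area (measured as 1.25
#' nondimensional units in default simulations). These two numbers place a
#' parameter set on the vertex-model ground-state phase diagram.
#'
#' @param lambda_bar,gamma_bar dimensionless tension and contractility.
#' @param A0 reference (cycle-averaged) target area, > 0.
#' @return a `vm_nd_params` list.
#' @export
nondimensional_params <- function(lambda_bar, gamma_bar, A0 = 1.25) {
  stopifnot(A0 > 0)
  structure(list(lambda_bar = lambda_bar, gamma_bar = gamma_bar, A0 = A0),
            class = "vm_nd_params")
}

#' @rdname nondimensional_params
#' @param params a [mechanical_params()] object.
#' @export
normalise_parameters <- function(params, A0 = 1.25) {
  nondimensional_params(params$Lambda / (params$K * A0^1.5),
                        params$Gamma / (params$K * A0), A0)
}

#' @rdname nondimensional_params
#' @param nd a `vm_nd_params` object.
#' @param K,mu,dt passed to [mechanical_params()].
#' @export
denormalise_parameters <- function(nd, K = 1, mu = 1, dt = 1.017e-3) {
  mechanical_params(K = K, Lambda = nd$lambda_bar * K * nd$A0^1.5,
                    Gamma = nd$gamma_bar * K * nd$A0, mu = mu, dt = dt)
}

#' Mechanical parameter presets
#'
#' The six `(lambda_bar, gamma_bar)` points used throughout the package:
#' I (-0.4, 0.14), II (-0.2, 0.12), III (-0.3, 0.1), IV (-0.05, 0.065),
#' V (0.075, 0.04), VI (0.15, 0.02), all referenced to A0 = 1.25. All six lie
#' in the epithelial (hexagonal-solid) regions of the phase diagram.
#'
#' @param name preset name, `"I"` to `"VI"`.
#' @return a `vm_nd_params` object.
#' @export
preset_params <- function(name = "V") {
  tbl <- list(I = c(-0.4, 0.14), II = c(-0.2, 0.12), III = c(-0.3, 0.1),
              IV = c(-0.05, 0.065), V = c(0.075, 0.04), VI = c(0.15, 0.02))
  p <- tbl[[match.arg(name, names(tbl))]]
  nondimensional_params(p[1], p[2])
}

#' Tissue energy
#'
#' Direct term-by-term evaluation of the vertex-model energy in R (one pass
#' over cells, each junction counted once). Used as the reference for the
#' finite-difference validation of the analytic forces.
#'
#' @param mesh a `vm_mesh`.
#' @param params a [mechanical_params()] object.
#' @param targets numeric vector of per-cell target areas `A0_alpha(t)`.
#' @return scalar energy.
#' @export
energy <- function(mesh, params, targets) {
  if (length(targets) != n_cells(mesh)) {
    stop("one target area per cell is required")
  }
  E <- 0
  for (a in seq_len(n_cells(mesh))) {
    A <- cell_area(mesh, a)
    P <- cell_perimeter(mesh, a)
    # Lambda/2 per cell-side: every junction is traversed by exactly 2 loops
    E <- E + 0.5 * params$K * (A - targets[a])^2 +
      0.5 * params$Gamma * P^2 + 0.5 * params$Lambda * P
  }
  E
}

#' Forces on all vertices
#'
#' Analytic gradient `F_i = -dE/dr_i` of the vertex-model energy (shoelace
#' area gradient, edge-direction tension and perimeter-contractility
#' gradients), minimum-image consistent. Also returns per-cell areas and
#' perimeters, per-loop-position edge lengths, the energy, and the
#' generalised gradients `dE/dL` under uniform dilation of each box axis
#' (consumed by the global drag dynamics in [step_scales()]).
#'
#' @param mesh a `vm_mesh`.
#' @param params a [mechanical_params()] object.
#' @param targets per-cell target areas.
#' @return list with `F` (`N_v x 2`), `area`, `perim`, `elen`, `gLx`, `gLy`,
#'   `energy`.
#' @export
vertex_forces <- function(mesh, params, targets) {
  if (length(targets) != n_cells(mesh)) {
    stop("one target area per cell is required")
  }
  k <- vm_kernel(mesh$v, mesh$flat$idx0, mesh$flat$ptr0,
                 mesh$box[1], mesh$box[2],
                 params$K, params$Lambda, params$Gamma, as.numeric(targets))
  list(F = cbind(k$fx, k$fy), area = k$area, perim = k$perim, elen = k$elen,
       gLx = k$gLx, gLy = k$gLy, energy = k$energy)
}

#' One explicit Euler step of the overdamped vertex dynamics
#'
#' `r_i <- r_i + (dt/mu) F_i`, wrapped into the periodic box.
#'
#' @param mesh a `vm_mesh`.
#' @param forces result of [vertex_forces()] (or any `N_v x 2` matrix).
#' @param params a [mechanical_params()] object.
#' @return the moved mesh.
#' @export
step_vertices <- function(mesh, forces, params) {
  F <- if (is.list(forces)) forces$F else forces
  disp <- (params$dt / params$mu) * F
  if (max(abs(disp)) > min(mesh$box) / 4) {
    stop(sprintf("vertex displacement %.3g exceeds box/4: reduce dt",
                 max(abs(disp))))
  }
  mesh$v <- cbind((mesh$v[, 1] + disp[, 1]) %% mesh$box[1],
                  (mesh$v[, 2] + disp[, 2]) %% mesh$box[2])
  mesh
}

# single-cell energy of a regular hexagon with side s, unit reference area,
# in units of K A0^2; c = area of unit-side hexagon
hex_cell_energy <- function(s, lambda_bar, gamma_bar) {
  cc <- 3 * sqrt(3) / 2
  0.5 * (cc * s^2 - 1)^2 + 18 * gamma_bar * s^2 + 3 * lambda_bar * s
}

#' Ground-state phase region of a parameter set
#'
#' Classifies `(lambda_bar, gamma_bar)` by the hexagonal-ground-state
#' analysis of the standard vertex model: the network is *soft* (region I)
#' when the preferred perimeter `-lambda_bar/(2 gamma_bar)` exceeds the
#' perimeter of the unit-area regular hexagon (shape degeneracy, no shear
#' rigidity), *collapsed* (region IV) when the single-cell energy of a
#' regular hexagon is minimised at zero size, and otherwise a solid with
#' hexagonal ground state: region II for non-positive tension, region III
#' for positive tension. Regions II and III are the epithelial regimes; all
#' six presets fall there.
#'
#' @param nd a [nondimensional_params()] object.
#' @return one of `"I_soft"`, `"II_hexagonal"`, `"III_tense"`,
#'   `"IV_collapsed"`, with attribute `epithelial` (logical).
#' @export
classify_phase_region <- function(nd) {
  lb <- nd$lambda_bar; gb <- nd$gamma_bar
  p_hex <- 6 / sqrt(3 * sqrt(3) / 2)     # perimeter of unit-area hexagon
  lab <- if (gb < 0) {
    "I_soft"
  } else if (lb <= 0) {
    if (gb == 0 || -lb / (2 * gb) >= p_hex) "I_soft" else "II_hexagonal"
  } else {
    opt <- stats::optimize(hex_cell_energy, c(1e-8, 3),
                           lambda_bar = lb, gamma_bar = gb)
    e0 <- hex_cell_energy(0, lb, gb)
    if (opt$objective < e0 && opt$minimum > 1e-4) "III_tense" else "IV_collapsed"
  }
  structure(lab, epithelial = lab %in% c("II_hexagonal", "III_tense"))
}
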