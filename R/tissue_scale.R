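#' Torus scale state
#'
#' The tissue is a torus with DV radius `R` (circumference `L_DV = 2 pi R`)
#' and AP radius `H` (`L_AP = 2 pi H`). Expansion of each radius is resisted
#' by a per-cell drag with coefficients `mu_dv` (mu') and `mu_ap` (mu'');
#' `mu_ap/mu_dv > 1` makes AP growth harder and drives DV-biased anisotropic
#' growth.
#'
#' @param R,H torus radii (nondimensional length), > 0.
#' @param mu_dv,mu_ap drag coefficients (defaults 0.02 and 1).
#' @return a `vm_scale` list.
#' @export
torus_scale <- function(R, H, mu_dv = 0.02, mu_ap = 1) {
  stopifnot(R > 0, H > 0, mu_dv > 0, mu_ap > 0)
  structure(list(R = R, H = H, mu_dv = mu_dv, mu_ap = mu_ap),
            class = "vm_scale")
}

#' @rdname torus_scale
#' @param mesh a `vm_mesh` (radii from its box).
#' @export
scale_from_mesh <- function(mesh, mu_dv = 0.02, mu_ap = 1) {
  torus_scale(mesh$box[1] / (2 * pi), mesh$box[2] / (2 * pi), mu_dv, mu_ap)
}

#' Generalised forces on the torus radii
#'
#' `F_R = -dE/dR` and `F_H = -dE/dH` at fixed angular vertex coordinates
#' (`x_i = R theta_i`), i.e. the conjugate forces of a uniform affine
#' dilation of each axis, obtained by the exact chain rule through cell
#' areas and minimum-image edge lengths.
#'
#' @param mesh a `vm_mesh`.
#' @param params a [mechanical_params()] object.
#' @param targets per-cell target areas.
#' @return list with `F_R`, `F_H`.
#' @export
scale_forces <- function(mesh, params, targets) {
  fr <- vertex_forces(mesh, params, targets)
  list(F_R = -2 * pi * fr$gLx, F_H = -2 * pi * fr$gLy)
}

#' One Euler step of the global growth dynamics
#'
#' `dR/dt = F_R / (2 mu' N_c)` and `dH/dt = F_H / (2 mu'' N_c)`: each cell
#' contributes a drag `2 mu` against radial expansion, so total drag scales
#' with cell number. The caller must then rescale vertex positions affinely
#' (see [apply_scale()]).
#'
#' @param scale a [torus_scale()] object.
#' @param F_R,F_H generalised forces from [scale_forces()].
#' @param N_c current cell count.
#' @param dt time step.
#' @return updated `vm_scale`.
#' @export
step_scales <- function(scale, F_R, F_H, N_c, dt) {
  dR <- dt * F_R / (2 * scale$mu_dv * N_c)
  dH <- dt * F_H / (2 * scale$mu_ap * N_c)
  # stability safeguard for collapsing tissues (few, shrinking cells):
  # cap the per-step relative change of each radius at 5%
  dR <- sign(dR) * min(abs(dR), 0.05 * scale$R)
  dH <- sign(dH) * min(abs(dH), 0.05 * scale$H)
  scale$R <- scale$R + dR
  scale$H <- scale$H + dH
  if (scale$R <= 0 || scale$H <= 0) {
    stop("torus radius driven non-positive: unstable growth step")
  }
  scale
}

#' Affinely rescale a mesh to a new box
#'
#' Vertex coordinates are multiplied by the ratio of new to old box lengths
#' in each axis (angular coordinates are preserved).
#'
#' @param mesh a `vm_mesh`.
#' @param new_box target `(L_DV, L_AP)`.
#' @return rescaled mesh.
#' @export
apply_scale <- function(mesh, new_box) {
  s <- new_box / mesh$box
  mesh$v <- cbind(mesh$v[, 1] * s[1], mesh$v[, 2] * s[2])
  mesh$box <- as.numeric(new_box)
  mesh
}

#' Whole-tissue AP/DV aspect ratio
#' @param scale a [torus_scale()] object (or a `vm_mesh`).
#' @return `H / R`, identically `L_AP / L_DV` of the box.
#' @export
tissue_aspect_ratio <- function(scale) {
  if (inherits(scale, "vm_mesh")) return(scale$box[2] / scale$box[1])
  scale$H / scale$R
}
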