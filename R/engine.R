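#' Simulation configuration
#'
#' Collects every tunable of a neuroepithelium simulation. Mechanical
#' parameters are given as a named preset (`"I"`..`"VI"`) or explicitly as
#' `(lambda_bar, gamma_bar)`; all other defaults reproduce the standard
#' study conditions: 13 h cell cycle, drags `mu' = 0.02`, `mu'' = 1`,
#' 30 h equilibration followed by 48 h of tracked growth, and (when a pMN
#' domain is present) a 30% DV band differentiating at 0.1 per hour.
#'
#' @param preset mechanical preset name, ignored if `lambda_bar` is given.
#' @param lambda_bar,gamma_bar explicit dimensionless mechanics.
#' @param n_rows,n_cols initial hexagonal grid (10 x 10, or 15 x 15 for
#'   two-domain runs).
#' @param t_T_hours mean total cell cycle in hours.
#' @param p_G1,p_SG2,p_M cell-cycle phase proportions.
#' @param A_c critical division area (nondimensional).
#' @param g_sd_frac growth-rate spread as fraction of the mean.
#' @param equilibrate_hours,run_hours durations of the equilibration and
#'   tracked phases (biological time).
#' @param dt Euler step in nondimensional time.
#' @param mu_dv,mu_ap global drag coefficients (mu', mu'').
#' @param pmn_fraction initial DV fraction of the pMN band (0 = no band).
#' @param diff_rate_per_hour differentiation hazard; applied to the pMN band
#'   if `pmn_fraction > 0`, otherwise uniformly to the whole tissue.
#' @param t1_threshold_fraction,l_new see [topology_params()].
#' @param snapshot_every_hours cadence of stored geometry snapshots.
#' @param seed integer seed (`NULL` = leave RNG state alone).
#' @param track_clones record founder clones from the end of equilibration.
#' @param A0_ref reference target area for nondimensionalising mechanics.
#' @param interp apicobasal interpolant for the target area.
#' @return a `vm_config` list.
#' @export
simulation_config <- function(preset = "V", lambda_bar = NULL, gamma_bar = NULL,
                              n_rows = 10, n_cols = 10,
                              t_T_hours = 13, p_G1 = 0.55, p_SG2 = 0.40,
                              p_M = 0.05, A_c = 1.5, g_sd_frac = 0.2,
                              equilibrate_hours = 30, run_hours = 48,
                              dt = 0.02, mu_dv = 0.02, mu_ap = 1,
                              pmn_fraction = 0, diff_rate_per_hour = 0,
                              t1_threshold_fraction = 0.03, l_new = NULL,
                              snapshot_every_hours = 6, seed = NULL,
                              track_clones = TRUE, A0_ref = 1.25,
                              interp = apical_interpolant) {
  stopifnot(equilibrate_hours >= 0, run_hours >= 0, pmn_fraction >= 0,
            pmn_fraction <= 1, diff_rate_per_hour >= 0)
  if (is.null(lambda_bar)) {
    nd <- preset_params(preset)
    lambda_bar <- nd$lambda_bar; gamma_bar <- nd$gamma_bar
  }
  nd <- nondimensional_params(lambda_bar, gamma_bar, A0_ref)
  structure(list(
    nd = nd, mech = denormalise_parameters(nd, dt = dt),
    n_rows = n_rows, n_cols = n_cols,
    phases = cell_cycle_phases(t_T_hours, p_G1, p_SG2, p_M),
    rule = division_rule(A_c), g_sd_frac = g_sd_frac,
    equilibrate_hours = equilibrate_hours, run_hours = run_hours,
    mu_dv = mu_dv, mu_ap = mu_ap,
    pmn_fraction = pmn_fraction, diff_rate_per_hour = diff_rate_per_hour,
    topo = topology_params(t1_threshold_fraction, l_new),
    snapshot_every_hours = snapshot_every_hours, seed = seed,
    track_clones = track_clones, interp = interp
  ), class = "vm_config")
}

#' Designate the pMN band
#'
#' Labels every cell whose centroid DV coordinate lies in a contiguous band
#' of width `fraction * L_DV` (centred mid-box) as pMN. Membership is
#' assigned once and inherited by daughters: the band is only the initial
#' condition of a lineage label, matching the biological identity of the
#' progenitor population.
#'
#' @param mesh a `vm_mesh`.
#' @param fraction DV fraction of the band, in `[0, 1]`.
#' @return logical vector, `TRUE` for pMN cells.
#' @export
designate_pmn <- function(mesh, fraction = 0.30) {
  stopifnot(fraction >= 0, fraction <= 1)
  if (fraction == 0) return(rep(FALSE, n_cells(mesh)))
  cx <- cell_centroids(mesh)[, 1]
  abs(wrap_delta(cx - mesh$box[1] / 2, mesh$box[1])) <= fraction * mesh$box[1] / 2
}

# fresh per-cell state for a newly built tissue; ages uniform over one cycle
# so divisions start asynchronously
new_state <- function(n, cfg) {
  list(t0 = -stats::runif(n) * cfg$phases$t_T,
       g = sample_growth_rate(n, cfg$phases, cfg$g_sd_frac),
       diff = rep(FALSE, n),
       clone = rep(NA_integer_, n),
       dom = rep(1L, n))            # 1 = pD, 2 = pMN
}

# does junction (i, j) currently exist?
junction_exists <- function(mesh, i, j) {
  for (a in cells_with_vertex(mesh, i)) {
    loop <- mesh$cells[[a]]
    p <- match1(i, loop)
    n <- length(loop)
    if (loop[p %% n + 1L] == j || loop[(p - 2L) %% n + 1L] == j) return(TRUE)
  }
  FALSE
}

# event buffers
new_events <- function() {
  list(div = list(t = numeric(0), clone = integer(0), dom = integer(0),
                  angle = numeric(0)),
       t1 = list(t = numeric(0), angle_old = numeric(0), angle_new = numeric(0),
                 dom = integer(0)),
       mark = list(t = numeric(0), dom = integer(0)),
       extrude = list(t = numeric(0), dom = integer(0)))
}

# One simulation phase: forces -> vertex Euler step -> scale step ->
# differentiation marking -> divisions -> short-edge T1s/removals.
run_phase <- function(mesh, st, scale, cfg, duration_units, diff_rate,
                      t_start, snapshots = NULL) {
  mp <- cfg$mech
  ph <- cfg$phases
  thr <- cfg$topo$t1_threshold_fraction
  nsteps <- max(0L, as.integer(round(duration_units / mp$dt)))
  series <- matrix(NA_real_, nsteps, 4,
                   dimnames = list(NULL, c("t", "n_cells", "L_DV", "L_AP")))
  ev <- new_events()
  snap_every <- max(1L, as.integer(round(hours_to_units(cfg$snapshot_every_hours) / mp$dt)))
  t <- t_start

  for (step in seq_len(nsteps)) {
    # stop when the tissue is effectively extinct or has collapsed below
    # the validity domain of the minimum-image representation (cells must
    # stay well under half the box in both axes)
    if (n_cells(mesh) < 4L) break
    if (min(mesh$box) < 3 * sqrt(prod(mesh$box) / n_cells(mesh))) break
    t <- t + mp$dt
    tt <- t - st$t0
    A0 <- (1 + st$g * tt) * cfg$interp(apicobasal_position(tt, ph))
    A0[st$diff] <- 0

    fr <- vertex_forces(mesh, mp, A0)
    mesh <- step_vertices(mesh, fr, mp)

    old_box <- mesh$box
    scale <- step_scales(scale, -2 * pi * fr$gLx, -2 * pi * fr$gLy,
                         n_cells(mesh), mp$dt)
    mesh <- apply_scale(mesh, 2 * pi * c(scale$R, scale$H))

    # stochastic differentiation
    if (diff_rate > 0) {
      eligible <- if (cfg$pmn_fraction > 0) st$dom == 2L else rep(TRUE, length(st$diff))
      before <- st$diff
      st$diff <- mark_differentiating(st$diff, eligible, diff_rate, mp$dt)
      newly <- which(st$diff & !before)
      if (length(newly)) {
        ev$mark$t <- c(ev$mark$t, rep(units_to_hours(t), length(newly)))
        ev$mark$dom <- c(ev$mark$dom, st$dom[newly])
      }
    }

    # candidate short junctions, captured before topology changes
    lbar <- mean(fr$elen)
    short_flat <- which(fr$elen < thr * lbar)
    short_pairs <- NULL
    if (length(short_flat)) {
      from <- mesh$flat$idx0[short_flat] + 1L
      to <- flat_next_vertex(mesh$flat)[short_flat]
      sp <- cbind(pmin(from, to), pmax(from, to), fr$elen[short_flat])
      sp <- sp[!duplicated(sp[, 1:2, drop = FALSE]), , drop = FALSE]
      short_pairs <- sp[order(sp[, 3]), , drop = FALSE]
    }

    # divisions
    ready <- which(division_ready(tt, fr$area, ph, cfg$rule, st$diff))
    for (a in ready) {
      res <- divide_cell(mesh, a)
      mesh <- res$mesh
      d2 <- res$daughters[2]
      st$t0[a] <- t; st$t0[d2] <- t
      gs <- sample_growth_rate(2, ph, cfg$g_sd_frac)
      st$g[a] <- gs[1]; st$g[d2] <- gs[2]
      st$diff[d2] <- FALSE
      st$clone[d2] <- st$clone[a]
      st$dom[d2] <- st$dom[a]
      ev$div$t <- c(ev$div$t, units_to_hours(t))
      ev$div$clone <- c(ev$div$clone, st$clone[a])
      ev$div$dom <- c(ev$div$dom, st$dom[a])
      ev$div$angle <- c(ev$div$angle, res$new_edge_angle)
    }

    # T1 transitions: ascending length, one per edge; stop after a removal
    # because vertex renumbering invalidates the remaining pairs
    if (!is.null(short_pairs)) {
      l_new <- cfg$topo$l_new %||% (2 * thr * lbar)
      tp <- topology_params(thr, l_new)
      for (r in seq_len(nrow(short_pairs))) {
        i <- short_pairs[r, 1]; j <- short_pairs[r, 2]
        if (!junction_exists(mesh, i, j)) next
        dx <- wrap_delta(mesh$v[j, 1] - mesh$v[i, 1], mesh$box[1])
        dy <- wrap_delta(mesh$v[j, 2] - mesh$v[i, 2], mesh$box[2])
        if (sqrt(dx^2 + dy^2) >= thr * lbar) next
        m2 <- withCallingHandlers(
          t1_transition(mesh, c(i, j), tp),
          warning = function(w) invokeRestart("muffleWarning")
        )
        if (isTRUE(attr(m2, "skipped"))) next
        info <- attr(m2, "t1_info")
        removed <- attr(m2, "removed_cells")
        mesh <- m2
        # majority domain among the four involved cells (indices pre-removal)
        dom_t1 <- if (sum(st$dom[info$cells] == 2L) >= 2L) 2L else 1L
        ev$t1$t <- c(ev$t1$t, units_to_hours(t))
        ev$t1$angle_old <- c(ev$t1$angle_old, info$old_angle)
        ev$t1$angle_new <- c(ev$t1$angle_new, info$new_angle)
        ev$t1$dom <- c(ev$t1$dom, dom_t1)
        if (length(removed)) {
          for (rr in removed) {
            ev$extrude$t <- c(ev$extrude$t, units_to_hours(t))
            ev$extrude$dom <- c(ev$extrude$dom, st$dom[rr])
            st$t0 <- st$t0[-rr]; st$g <- st$g[-rr]
            st$diff <- st$diff[-rr]; st$clone <- st$clone[-rr]
            st$dom <- st$dom[-rr]
          }
          break
        }
      }
    }

    series[step, ] <- c(units_to_hours(t), n_cells(mesh), mesh$box)
    if (!is.null(snapshots) && step %% snap_every == 0L) {
      snapshots[[length(snapshots) + 1L]] <-
        list(t_hours = units_to_hours(t),
             table = geometry_table(mesh, st), box = mesh$box)
    }
  }
  series <- series[!is.na(series[, 1]), , drop = FALSE]
  list(mesh = mesh, st = st, scale = scale, t = t, series = series, ev = ev,
       snapshots = snapshots)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a neuroepithelium simulation
#'
#' Full protocol: build the hexagonal tissue, equilibrate it under the
#' mechanics (no differentiation, no clone tracking), reset the clock,
#' designate founder clones (and the pMN band when configured), then run the
#' tracked phase with stochastic differentiation, divisions, T1
#' rearrangements and global anisotropic growth. Deterministic given
#' `config$seed`.
#'
#' @param config a [simulation_config()] object.
#' @return a `vm_sim` object: final `mesh`, per-cell `state` tibble, torus
#'   `scale`, `events` (tibbles: `divisions`, `t1`, `markings`,
#'   `extrusions`), per-step `series` (cell count and box lengths), periodic
#'   geometry `snapshots`, founder-clone records `clones`, and the `config`.
#' @export
run_simulation <- function(config) {
  if (!is.null(config$seed)) set.seed(config$seed)
  mesh <- build_hexagonal_tissue(config$n_rows, config$n_cols)
  st <- new_state(n_cells(mesh), config)

  # Equilibration prepares a disordered, isotropic steady state: drag is
  # symmetric (both axes at mu') so the box grows without developing
  # anisotropy; the anisotropic drag models the embryonic constraints that
  # act during the tracked developmental window.
  scale <- scale_from_mesh(mesh, config$mu_dv, config$mu_dv)
  eq <- run_phase(mesh, st, scale, config,
                  hours_to_units(config$equilibrate_hours),
                  diff_rate = 0, t_start = 0)
  mesh <- eq$mesh; st <- eq$st
  scale <- torus_scale(eq$scale$R, eq$scale$H, config$mu_dv, config$mu_ap)

  # time reset: the equilibrated vertex distribution is the starting point
  st$t0 <- st$t0 - eq$t
  if (config$track_clones) st$clone <- seq_along(st$t0)
  if (config$pmn_fraction > 0) {
    st$dom <- ifelse(designate_pmn(mesh, config$pmn_fraction), 2L, 1L)
  }
  founder_dom <- st$dom

  main <- run_phase(mesh, st, scale, config,
                    hours_to_units(config$run_hours),
                    diff_rate = config$diff_rate_per_hour,
                    t_start = 0, snapshots = list())

  ev <- main$ev
  doms <- c("pD", "pMN")
  events <- list(
    divisions = tibble::tibble(t_hours = ev$div$t, clone = ev$div$clone,
                               domain = doms[ev$div$dom],
                               new_edge_angle = ev$div$angle),
    t1 = tibble::tibble(t_hours = ev$t1$t, angle_old = ev$t1$angle_old,
                        angle_new = ev$t1$angle_new, domain = doms[ev$t1$dom]),
    markings = tibble::tibble(t_hours = ev$mark$t, domain = doms[ev$mark$dom]),
    extrusions = tibble::tibble(t_hours = ev$extrude$t,
                                domain = doms[ev$extrude$dom])
  )
  state <- tibble::tibble(
    cell = seq_along(main$st$t0), t0 = main$st$t0, g = main$st$g,
    differentiating = main$st$diff, clone = main$st$clone,
    domain = doms[main$st$dom]
  )
  out <- structure(list(
    mesh = main$mesh, state = state, scale = main$scale, config = config,
    t_hours = units_to_hours(main$t), events = events,
    series = tibble::as_tibble(as.data.frame(main$series)),
    snapshots = main$snapshots,
    founder_domain = tibble::tibble(clone = seq_along(founder_dom),
                                    domain = doms[founder_dom])
  ), class = "vm_sim")
  out$clones <- if (config$track_clones) track_clones(out) else NULL
  out
}

#' @export
print.vm_sim <- function(x, ...) {
  cat(sprintf("<vm_sim> %d cells after %.1f h (+%.0f h equilibration); box %.2f x %.2f, AP/DV %.3f\n",
              n_cells(x$mesh), x$t_hours, x$config$equilibrate_hours,
              x$mesh$box[1], x$mesh$box[2], tissue_aspect_ratio(x$mesh)))
  cat(sprintf("  events: %d divisions, %d T1, %d markings, %d extrusions\n",
              nrow(x$events$divisions), nrow(x$events$t1),
              nrow(x$events$markings), nrow(x$events$extrusions)))
  invisible(x)
}

# circular extent of a point set on a periodic interval: total length minus
# the largest empty gap; equals max - min after minimum-image unwrapping for
# any cluster narrower than the box
circular_extent <- function(x, L) {
  if (length(x) < 2) return(0)
  s <- sort(x %% L)
  gaps <- c(diff(s), s[1] + L - s[length(s)])
  L - max(gaps)
}

#' Founder clone records
#'
#' For each founder clone: surviving member count and the AP and DV extents
#' of the union of member vertices (minimum-image consistent, so clones
#' straddling the periodic seam are measured correctly). Clones wider than
#' half the box are flagged (`wrapped`), as their extent is ambiguous under
#' periodicity.
#'
#' @param sim a `vm_sim` object.
#' @return tibble with `clone`, `n_cells`, `dv_extent`, `ap_extent`,
#'   `domain` (founder domain), `wrapped`.
#' @export
track_clones <- function(sim) {
  st <- sim$state
  mesh <- sim$mesh
  ids <- sort(unique(st$clone[!is.na(st$clone)]))
  res <- lapply(ids, function(cl) {
    cells <- which(st$clone == cl)
    vids <- unique(unlist(mesh$cells[cells], use.names = FALSE))
    dv <- circular_extent(mesh$v[vids, 1], mesh$box[1])
    ap <- circular_extent(mesh$v[vids, 2], mesh$box[2])
    tibble::tibble(clone = cl, n_cells = length(cells), dv_extent = dv,
                   ap_extent = ap,
                   wrapped = dv > mesh$box[1] / 2 || ap > mesh$box[2] / 2)
  })
  out <- dplyr::bind_rows(res)
  dplyr::left_join(out, sim$founder_domain, by = "clone")
}
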