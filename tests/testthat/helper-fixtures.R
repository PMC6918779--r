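# Small meshes and oracles shared across test files.

# A single polygonal "cell" in a large box: not a valid tiling (no audit),
# but exercises the per-cell geometry exactly.
single_cell_mesh <- function(poly, box = c(100, 100)) {
  vm_mesh(poly, list(seq_len(nrow(poly))), box)
}

unit_square_poly <- function(origin = c(1, 1)) {
  cbind(origin[1] + c(0, 1, 1, 0), origin[2] + c(0, 0, 1, 1))
}

regular_hexagon_poly <- function(s = 1, centre = c(5, 5), phase = 0) {
  th <- phase + seq(0, by = pi / 3, length.out = 6)
  cbind(centre[1] + s * cos(th), centre[2] + s * sin(th))
}

# jittered periodic tissue for gradient checks
jittered_tissue <- function(nr = 4, nc = 4, sd = 0.05) {
  m <- build_hexagonal_tissue(nr, nc)
  m$v <- m$v + matrix(stats::rnorm(nrow(m$v) * 2, 0, sd), ncol = 2)
  m$v[, 1] <- m$v[, 1] %% m$box[1]
  m$v[, 2] <- m$v[, 2] %% m$box[2]
  m
}

# independent central finite-difference gradient of the R-side energy
fd_forces <- function(mesh, params, targets, h = 1e-6) {
  Fm <- matrix(0, n_vertices(mesh), 2)
  for (i in seq_len(n_vertices(mesh))) {
    for (d in 1:2) {
      mp <- mesh; mp$v[i, d] <- mp$v[i, d] + h
      mm <- mesh; mm$v[i, d] <- mm$v[i, d] - h
      Fm[i, d] <- -(energy(mp, params, targets) - energy(mm, params, targets)) / (2 * h)
    }
  }
  Fm
}

# cache for the expensive protocol simulations used by the acceptance tests
.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(name, cfg) {
  if (!exists(name, envir = .sim_cache)) {
    assign(name, run_simulation(cfg), envir = .sim_cache)
  }
  get(name, envir = .sim_cache)
}

# study-condition runs, scaled to a 10x10 grid for the test suite
sim_no_diff <- function() {
  cached_sim("no_diff", simulation_config(
    preset = "V", n_rows = 10, n_cols = 10, equilibrate_hours = 30,
    run_hours = 48, dt = 0.02, seed = 101
  ))
}

sim_two_domain <- function() {
  cached_sim("two_domain", simulation_config(
    preset = "V", n_rows = 15, n_cols = 15, equilibrate_hours = 30,
    run_hours = 48, dt = 0.02, seed = 202,
    pmn_fraction = 0.30, diff_rate_per_hour = 0.1
  ))
}

sim_uniform_diff <- function() {
  cached_sim("uniform_diff", simulation_config(
    preset = "V", n_rows = 15, n_cols = 15, equilibrate_hours = 30,
    run_hours = 48, dt = 0.02, seed = 303, track_clones = FALSE,
    pmn_fraction = 0, diff_rate_per_hour = 0.1
  ))
}

# final-state mean target area of a simulation
final_mean_target <- function(sim) {
  st <- sim$state
  tt <- hours_to_units(sim$t_hours) - st$t0
  ph <- sim$config$phases
  A0 <- (1 + st$g * tt) * apical_interpolant(apicobasal_position(tt, ph))
  A0[st$differentiating] <- 0
  mean(A0)
}

# T1 rate in the last hour during which the tissue is still a valid
# epithelium: the minimum-image mesh representation requires cells to be
# well below half the box, so measurement stops once either box length
# falls under 4 mean cell diameters (only collapsing tissues ever hit this)
t1_rate_end <- function(sim) {
  s <- sim$series
  dia <- sqrt(s$L_DV * s$L_AP / s$n_cells)
  ok <- s$t[pmin(s$L_DV, s$L_AP) >= 4 * dia]
  t_end <- if (length(ok)) max(ok) else s$t[1] + 1
  nbar <- mean(s$n_cells[s$t > t_end - 1 & s$t <= t_end])
  t1_statistics(sim$events$t1, 1, nbar, t_end = t_end)$rate
}

# division events / (mean cell count * window), over the trailing window
measured_lambda <- function(sim, window = 10) {
  d <- sum(sim$events$divisions$t_hours > sim$t_hours - window)
  nbar <- mean(sim$series$n_cells[sim$series$t > sim$t_hours - window])
  proliferation_rate(d, nbar, window)
}

# DV extent of surviving pMN cells as a fraction of tissue DV length
pmn_dv_fraction <- function(sim) {
  st <- sim$state
  pmn <- which(st$domain == "pMN")
  if (!length(pmn)) return(0)
  vids <- unique(unlist(sim$mesh$cells[pmn], use.names = FALSE))
  neurovertex:::circular_extent(sim$mesh$v[vids, 1], sim$mesh$box[1]) /
    sim$mesh$box[1]
}
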