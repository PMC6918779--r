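# Property-style suites over generated cases: gradient consistency,
# invariant preservation through long runs, ensemble symmetries.

test_that("analytic forces track finite differences over many random meshes", {
  set.seed(12)
  worst <- 0
  for (k in 1:12) {
    m <- jittered_tissue(3, 3, sd = stats::runif(1, 0.02, 0.1))
    p <- mechanical_params(K = stats::runif(1, 0.5, 2),
                           Lambda = stats::runif(1, -0.3, 0.3),
                           Gamma = stats::runif(1, 0, 0.12))
    tg <- stats::runif(n_cells(m), 0.6, 1.5)
    fr <- vertex_forces(m, p, tg)
    Ffd <- fd_forces(m, p, tg)
    worst <- max(worst, max(abs(fr$F - Ffd)) / max(abs(Ffd)))
  }
  expect_lt(worst, 1e-5)
})

test_that("long runs with every event type preserve all mesh invariants", {
  sim <- sim_two_domain()
  expect_length(topology_audit(sim$mesh), 0)
  expect_equal(mean(cell_sides(sim$mesh)), 6)   # exact, Euler on the torus
  areas <- vapply(seq_len(n_cells(sim$mesh)),
                  function(a) cell_area(sim$mesh, a), 0)
  expect_equal(sum(areas), prod(sim$mesh$box), tolerance = 1e-8)
})

test_that("without differentiation the population doubles roughly every cycle", {
  sim <- sim_no_diff()
  s <- sim$series
  k <- effective_growth_rate(s$n_cells[1], s$n_cells[nrow(s)], sim$t_hours)
  expect_equal(k, log(2) / 13, tolerance = 0.35)
  # the two proliferation estimators agree once cell loss is accounted
  # for: k counts net change, lambda counts divisions only, and the
  # difference is the (compression-driven) extrusion rate
  lam <- measured_lambda(sim, window = 10)
  k10 <- effective_growth_rate(
    s$n_cells[which.min(abs(s$t - (sim$t_hours - 10)))],
    s$n_cells[nrow(s)], 10)
  ext <- sum(sim$events$extrusions$t_hours > sim$t_hours - 10) /
    (mean(s$n_cells[s$t > sim$t_hours - 10]) * 10)
  expect_equal(lam - ext, k10, tolerance = 0.15)
})

test_that("clones form mostly coherent (connected) groups", {
  sim <- sim_no_diff()
  mesh <- sim$mesh
  # cell adjacency from shared junctions
  fl <- mesh$flat
  from <- fl$cell_of
  key <- paste(pmin(fl$idx0 + 1L, neurovertex:::flat_next_vertex(fl)),
               pmax(fl$idx0 + 1L, neurovertex:::flat_next_vertex(fl)))
  nbr <- split(from, key)                     # two cells per junction
  adj <- do.call(rbind, nbr[lengths(nbr) == 2])
  connected <- function(cells) {
    if (length(cells) <= 1) return(TRUE)
    sub <- adj[adj[, 1] %in% cells & adj[, 2] %in% cells, , drop = FALSE]
    seen <- cells[1]
    repeat {
      nxt <- unique(c(sub[sub[, 1] %in% seen, 2], sub[sub[, 2] %in% seen, 1]))
      grown <- union(seen, nxt)
      if (length(grown) == length(seen)) break
      seen <- grown
    }
    length(seen) == length(cells)
  }
  st <- sim$state
  ids <- unique(st$clone)
  coh <- vapply(ids, function(cl) connected(which(st$clone == cl)), TRUE)
  # coherence threshold is this package's regression level: most clones
  # stay connected, with some fragmentation from intercalation at clone
  # boundaries and compression-driven extrusion
  expect_gt(mean(coh), 0.65)
})

test_that("the pMN band shrinks monotonically under differentiation", {
  sim <- sim_two_domain()
  fracs <- vapply(sim$snapshots, function(sn) {
    tb <- sn$table
    pmn <- which(tb$domain == "pMN")
    if (!length(pmn)) return(0)
    neurovertex:::circular_extent(tb$centroid_x[pmn], sn$box[1]) / sn$box[1]
  }, 0)
  # decreasing trend: negative rank correlation with time and net shrink
  expect_lt(stats::cor(seq_along(fracs), fracs, method = "spearman"), -0.7)
  expect_lt(fracs[length(fracs)], 0.65 * fracs[1])
})

test_that("symmetric drag produces no systematic growth anisotropy", {
  ratios <- vapply(c(11, 22, 33), function(seed) {
    cfg <- simulation_config(preset = "V", n_rows = 6, n_cols = 6,
                             equilibrate_hours = 0, run_hours = 20, dt = 0.02,
                             seed = seed, mu_dv = 0.02, mu_ap = 0.02,
                             track_clones = FALSE, snapshot_every_hours = 100)
    sim <- run_simulation(cfg)
    s <- sim$series
    log(tissue_aspect_ratio(sim$mesh) / (s$L_AP[1] / s$L_DV[1]))
  }, 0)
  # individual runs wander (the box aspect is a soft mode), but the
  # ensemble mean drift stays small
  expect_lt(abs(mean(ratios)), 0.35)
})

test_that("anisotropic drag keeps the aspect ratio inside its theoretical bounds", {
  sim <- sim_no_diff()
  b <- aspect_ratio_bounds(sim$config$mu_dv, sim$config$mu_ap)
  a <- tissue_aspect_ratio(sim$mesh)
  expect_gt(a, b["fast"])
  expect_lte(a, b["slow"])
  # and the AP/DV ratio decreases as the tissue grows
  s <- sim$series
  expect_lt(tissue_aspect_ratio(sim$mesh), s$L_AP[1] / s$L_DV[1])
})

test_that("slower proliferation yields more isotropic growth", {
  aspects <- vapply(c(13, 26, 52), function(tth) {
    cfg <- simulation_config(preset = "V", n_rows = 6, n_cols = 6,
                             t_T_hours = tth, equilibrate_hours = 10,
                             run_hours = 30, dt = 0.02, seed = 19,
                             track_clones = FALSE, snapshot_every_hours = 100)
    tissue_aspect_ratio(run_simulation(cfg)$mesh)
  }, 0)
  # monotone trend over the three rates: doubling the cycle time moves the
  # AP/DV ratio toward 1
  expect_true(all(diff(aspects) > 0))
})

test_that("division angles are uniform while pD T1 new edges are DV-biased", {
  sim <- sim_no_diff()
  dd <- division_angle_distribution(sim$events$divisions)
  expect_gt(dd$p_value, 0.01)
  ang <- fold_angle(sim$events$t1$angle_new)
  # sign test for DV bias: more new edges closer to DV than to AP
  n_dv <- sum(ang < pi / 4); n_tot <- length(ang)
  expect_gt(n_dv / n_tot, 0.5)
  expect_lt(stats::binom.test(n_dv, n_tot, 0.5,
                              alternative = "greater")$p.value, 0.05)
})

test_that("observables are insensitive to halving the time step", {
  run_short <- function(dt) {
    cfg <- simulation_config(preset = "V", n_rows = 6, n_cols = 6,
                             equilibrate_hours = 8, run_hours = 10, dt = dt,
                             seed = 55, track_clones = FALSE,
                             snapshot_every_hours = 100)
    sim <- run_simulation(cfg)
    fr <- vertex_forces(sim$mesh, sim$config$mech, rep(1, n_cells(sim$mesh)))
    c(mean_area = mean(fr$area), n = n_cells(sim$mesh),
      aspect = tissue_aspect_ratio(sim$mesh))
  }
  a <- run_short(0.02)
  b <- run_short(0.01)
  expect_equal(a[["mean_area"]], b[["mean_area"]], tolerance = 0.1)
  expect_equal(a[["n"]], b[["n"]], tolerance = 0.15)
  expect_equal(a[["aspect"]], b[["aspect"]], tolerance = 0.15)
})
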