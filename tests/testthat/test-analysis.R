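test_that("elongation matches closed forms and is rotation invariant", {
  expect_equal(cell_elongation(regular_hexagon_poly(1)), 1, tolerance = 1e-9)
  rect <- cbind(c(-1, 1, 1, -1), c(-0.5, -0.5, 0.5, 0.5))
  expect_equal(cell_elongation(rect), 2, tolerance = 1e-12)
  th <- 0.7
  rot <- rect %*% rbind(c(cos(th), sin(th)), c(-sin(th), cos(th)))
  expect_equal(cell_elongation(rot), 2, tolerance = 1e-9)
  expect_error(cell_elongation(cbind(0:3, 0:3)), "degenerate|collinear")
})

test_that("orientation angle is measured from the DV axis", {
  dv_rect <- cbind(c(-2, 2, 2, -2), c(-0.5, -0.5, 0.5, 0.5))  # long axis DV
  expect_equal(cell_orientation_angle(dv_rect), 0, tolerance = 1e-9)
  ap_rect <- dv_rect[, 2:1]                                    # long axis AP
  expect_equal(abs(cell_orientation_angle(ap_rect)), pi / 2, tolerance = 1e-9)
  th <- pi / 4
  rot <- dv_rect %*% rbind(c(cos(th), sin(th)), c(-sin(th), cos(th)))
  expect_equal(abs(cell_orientation_angle(rot)), pi / 4, tolerance = 1e-9)
  # isotropic shapes are flagged, not given an arbitrary axis
  expect_true(is.na(cell_orientation_angle(unit_square_poly())))
})

test_that("DV length is the x-extent, seam-safe through cell_polygon", {
  expect_equal(cell_dv_length(unit_square_poly()), 1)
  # flat-topped regular hexagon spans 2s in x; pointy-topped spans sqrt(3) s
  s <- 0.8
  expect_equal(cell_dv_length(regular_hexagon_poly(s, phase = 0)), 2 * s)
  expect_equal(cell_dv_length(regular_hexagon_poly(s, phase = pi / 6)),
               sqrt(3) * s, tolerance = 1e-12)
  # a seam-straddling cell matches its translated copy
  m <- build_hexagonal_tissue(4, 4)
  seam <- which(vapply(seq_len(n_cells(m)), function(a) {
    any(abs(diff(m$v[m$cells[[a]], 1])) > m$box[1] / 2)
  }, TRUE))[1]
  p1 <- cell_polygon(m, seam)
  mt <- m
  mt$v[, 1] <- (mt$v[, 1] + m$box[1] / 3) %% m$box[1]
  expect_equal(cell_dv_length(cell_polygon(mt, seam)), cell_dv_length(p1),
               tolerance = 1e-9)
})

test_that("K-S statistic matches enumeration and stats::ks.test", {
  expect_equal(ks_statistic(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(ks_statistic(1:3, 4:6), 1)            # disjoint supports
  expect_equal(ks_statistic(c(1, 2, 3), c(1, 2, 4)), 1 / 3)
  set.seed(8)
  a <- stats::rnorm(40); b <- stats::rnorm(60, 0.5)
  expect_equal(ks_statistic(a, b),
               unname(suppressWarnings(stats::ks.test(a, b)$statistic)),
               tolerance = 1e-12)
  expect_error(ks_statistic(numeric(0), 1:3), "empty")
  # replicate averaging: identical replicate sets still score 0
  reps <- list(stats::rnorm(30), stats::rnorm(30, 1))
  expect_equal(ks_statistic(reps, reps), 0)
})

test_that("geometry similarity score behaves as a distance-like screen score", {
  ref <- synthetic_geometry_fixture(400, seed = 1)
  expect_equal(as.numeric(geometry_similarity_score(ref, ref)), 0)

  # shifting areas by +3 sd strictly increases the score
  shifted <- ref
  shifted$area <- shifted$area + 3 * stats::sd(ref$area)
  expect_gt(as.numeric(geometry_similarity_score(shifted, ref)), 0)

  # unit mismatch must be explicit
  sim_tbl <- ref
  attr(sim_tbl, "units") <- "nondim"
  expect_error(geometry_similarity_score(sim_tbl, ref), "unit mismatch")
  expect_silent(geometry_similarity_score(sim_tbl, ref, area_scale = 23))

  # hand-computed five-component mean on a tiny table
  t1 <- tibble::tibble(area = c(1, 2, 3), perimeter = c(4, 5, 6),
                       n_neighbours = c(5, 6, 7))
  t2 <- tibble::tibble(area = c(1, 2, 4), perimeter = c(4, 5, 6),
                       n_neighbours = c(5, 6, 7))
  attr(t1, "units") <- "nondim"; attr(t2, "units") <- "nondim"
  got <- geometry_similarity_score(t1, t2)
  hand <- mean(c(1 / 3, 0, 0,
                 abs(stats::sd(c(1, 2, 4)) - stats::sd(c(1, 2, 3))), 0))
  expect_equal(as.numeric(got), hand, tolerance = 1e-12)
})

test_that("tissue fit score is log-additive in DV change", {
  expect_equal(tissue_fit_score(5, 0.3, 5, 0.3), 0)
  expect_equal(tissue_fit_score(10, 0.3, 5, 0.3), log(2), tolerance = 1e-12)
  expect_equal(tissue_fit_score(c(5, 5), c(0.4, 0.2), 5, 0.3), 0.1)
  expect_error(tissue_fit_score(-1, 0.3, 5, 0.3), "positive")
})

test_that("clone spread ratio applies the one-unit correction", {
  cl <- tibble::tibble(ap_extent = c(2, 3), dv_extent = c(5, 7))
  expect_equal(clone_spread_ratio(cl), (2.5 - 1) / (6 - 1))
  iso <- tibble::tibble(ap_extent = c(2, 4), dv_extent = c(4, 2))
  expect_equal(clone_spread_ratio(iso), 1)
  tiny <- tibble::tibble(ap_extent = c(0.5, 0.6), dv_extent = c(2, 3))
  expect_error(clone_spread_ratio(tiny), "too small")
  # antisymmetry: swapping AP and DV extents inverts the ratio
  sw <- tibble::tibble(ap_extent = cl$dv_extent, dv_extent = cl$ap_extent)
  expect_equal(clone_spread_ratio(sw), 1 / clone_spread_ratio(cl))
})

test_that("proliferation and effective growth rates follow their definitions", {
  expect_equal(proliferation_rate(5, 100, 1), 0.05)
  expect_equal(proliferation_rate(0, 50, 2), 0)
  expect_equal(effective_growth_rate(100, 200, 13), log(2) / 13)
  expect_equal(effective_growth_rate(80, 80, 5), 0)

  # pure-birth toy: lambda ~= k ~= ln 2 / t_T, starting from the stable
  # age distribution p(a) = 2 lambda 2^(-a/T) on [0, T]
  set.seed(21)
  t_T <- 13; n0 <- 400; horizon <- 6
  births <- c()
  pop <- -t_T * log2(1 - stats::runif(n0) / 2)  # inverse-CDF ages
  t <- 0; dt <- 0.05
  while (t < horizon) {
    t <- t + dt
    pop <- pop + dt
    due <- pop >= t_T
    births <- c(births, rep(t, sum(due)))
    pop[due] <- 0
    pop <- c(pop, rep(0, sum(due)))
  }
  lam <- proliferation_rate(length(births), (n0 + length(pop)) / 2, horizon)
  k <- effective_growth_rate(n0, length(pop), horizon)
  expect_equal(lam, k, tolerance = 0.15)
  expect_equal(lam, log(2) / t_T, tolerance = 0.1)
})

test_that("T1 statistics and angle folding", {
  ev <- tibble::tibble(t_hours = c(0.2, 0.5, 0.9, 1.4),
                       angle_old = 0, angle_new = c(0, pi / 2, pi, -pi / 3),
                       domain = "pD")
  out <- t1_statistics(ev[0, ], 1, 100)
  expect_equal(out$rate, 0)
  out <- t1_statistics(ev, window_hours = 1, n_bar = 100, t_end = 1.4)
  expect_equal(out$rate, 3 / 100)
  expect_equal(sort(out$angles), sort(c(pi / 2, 0, pi / 3)))
  expect_equal(fold_angle(c(0, pi, -pi / 2, 2.5)),
               c(0, 0, pi / 2, pi - 2.5), tolerance = 1e-12)
  # 38 events over one hour with 100 cells: the printed-style rate arithmetic
  ev38 <- tibble::tibble(t_hours = seq(0.01, 1, length.out = 38),
                         angle_old = 0, angle_new = 0, domain = "pD")
  expect_equal(t1_statistics(ev38, 1, 100, t_end = 1)$rate, 0.38)
})

test_that("division-angle uniformity test is calibrated", {
  set.seed(31)
  rejections <- 0
  for (k in 1:100) {
    ev <- tibble::tibble(t_hours = 1, clone = 1, domain = "pD",
                         new_edge_angle = stats::runif(80, -pi / 2, pi / 2))
    if (division_angle_distribution(ev)$p_value < 0.05) rejections <- rejections + 1
  }
  expect_lte(rejections, 5 + 4)   # ~5% nominal, allow sampling slack

  all_zero <- tibble::tibble(t_hours = 1, clone = 1, domain = "pD",
                             new_edge_angle = rep(0, 60))
  expect_lt(division_angle_distribution(all_zero)$p_value, 1e-6)
})

test_that("Lewis-law fit recovers linear class means", {
  tbl <- tibble::tibble(
    area = rep(c(0.6, 0.8, 1.0, 1.2, 1.4), each = 10),
    n_neighbours = rep(4:8, each = 10)
  )
  f <- lewis_law_fit(tbl)
  expect_equal(f$r_squared, 1, tolerance = 1e-9)
  expect_gt(f$slope, 0)
  td <- tidy(f)
  expect_equal(td$estimate[2], f$slope)

  const <- tibble::tibble(area = rep(1, 40), n_neighbours = rep(4:7, each = 10))
  expect_equal(lewis_law_fit(const)$slope, 0, tolerance = 1e-12)
  expect_error(lewis_law_fit(tibble::tibble(area = 1:6,
                                            n_neighbours = rep(6, 6))),
               "3 neighbour classes")
})

test_that("synthetic fixture reproduces requested moments and is seed-stable", {
  f1 <- synthetic_geometry_fixture(4000, mean_area = 23, sd_area = 8, seed = 42)
  f2 <- synthetic_geometry_fixture(4000, mean_area = 23, sd_area = 8, seed = 42)
  expect_identical(f1$area, f2$area)
  expect_lt(abs(mean(f1$area) - 23), 2 * 8 / sqrt(4000))
  expect_lt(abs(mean(f1$n_neighbours) - 6), 2 * 1.5 / sqrt(4000))
  expect_true(all(f1$elongation >= 1))
  expect_true(all(f1$n_neighbours >= 3))
  expect_equal(attr(f1, "units"), "um2")
  expect_error(synthetic_geometry_fixture(10, mean_area = 5, sd_area = 9),
               "infeasible")
})
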