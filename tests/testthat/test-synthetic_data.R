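# Generators with analytic ground truth.

test_that("make_cluster_trace validates input and honors degenerate chains", {
  expect_error(make_cluster_trace(matrix(c(0.5, 0.4, 0.5, 0.5), 2)), "sum to 1")
  expect_error(make_cluster_trace(matrix(1, 1, 2)), "square")
  const <- make_cluster_trace(diag(2), n_frames = 200, seed = 1)
  expect_identical(length(unique(const$series)), 1L)
})

test_that("2-state symmetric chain reproduces the geometric dwell law", {
  p_self <- 0.9
  P <- matrix(c(p_self, 1 - p_self, 1 - p_self, p_self), 2, byrow = TRUE)
  fi <- 0.1
  tr <- make_cluster_trace(P, n_frames = 1e5, frame_interval = fi, seed = 7)
  expect_equal(tr$ground_truth$mean_dwell_s, rep(fi / (1 - p_self), 2))
  segs <- dwell_segments(tr$series, fi)
  open <- segs[!segs$censored, ]
  m <- mean(open$duration_s)
  se <- sd(open$duration_s) / sqrt(nrow(open))
  expect_lt(abs(m - fi / (1 - p_self)), 3 * se)
})

test_that("stationary mode is recovered by most_possible_pattern", {
  # iid chain with stationary (0.3, 0.6, 0.1) over cluster numbers 0..2
  P <- matrix(rep(c(0.3, 0.6, 0.1), 3), 3, byrow = TRUE)
  tr <- make_cluster_trace(P, n_frames = 1e4, seed = 11)
  expect_identical(tr$ground_truth$mode, 1L)
  expect_equal(tr$ground_truth$stationary, c(0.3, 0.6, 0.1), tolerance = 1e-12)
  expect_identical(most_possible_pattern(tr$series)$mode, 1L)
})

test_that("make_cluster_trace is deterministic under a fixed seed", {
  P <- matrix(c(0.8, 0.2, 0.3, 0.7), 2, byrow = TRUE)
  a <- make_cluster_trace(P, n_frames = 500, seed = 3)
  b <- make_cluster_trace(P, n_frames = 500, seed = 3)
  expect_identical(a$frames, b$frames)
})

test_that("make_bond_graph builds exact components with 5 nm bonds", {
  cfg <- default_config()
  single <- make_bond_graph(1, cfg, seed = 1)
  expect_true(all(single$clat$leg_bond == 0))
  expect_identical(nrow(single$clat$pos), 1L)

  st <- make_bond_graph(c(12, 7), cfg, seed = 2)
  cf <- identify_clusters(st, min_cluster_size = 1)
  expect_identical(sort(cf$cluster_sizes), c(7L, 12L))
  geom <- do.call(site_geometry, cfg$site_geometry)
  bonded <- which(st$clat$leg_bond > 0, arr.ind = TRUE)
  expect_gt(nrow(bonded), 0)
  for (r in seq_len(nrow(bonded))) {
    i <- unname(bonded[r, 1]); k <- unname(bonded[r, 2])
    j <- st$clat$leg_bond[i, k]; kj <- st$clat$leg_bond_site[i, k]
    si <- clathrin_sites(list(center = st$clat$pos[i, ], quat = st$clat$quat[i, ]), geom)
    sj <- clathrin_sites(list(center = st$clat$pos[j, ], quat = st$clat$quat[j, ]), geom)
    expect_equal(sqrt(sum((si[k, ] - sj[kj, ])^2)), 5, tolerance = 1e-9)
  }
  expect_error(make_bond_graph(c(3, 0)), ">= 1")
})

test_that("make_point_pattern embeds exact brute-force neighbor counts", {
  one <- make_point_pattern(n = 1, seed = 1)
  expect_identical(attr(one, "neighbor_counts"), 0L)
  pat <- make_point_pattern(n = 60, domain_um = 4, seed = 5)
  expect_identical(neighbor_counts(cbind(pat$x_um, pat$y_um),
                                   attr(pat, "window_um")),
                   attr(pat, "neighbor_counts"))
  mat <- make_point_pattern(n = 80, placement = "matern", seed = 6)
  expect_identical(neighbor_counts(cbind(mat$x_um, mat$y_um),
                                   attr(mat, "window_um")),
                   attr(mat, "neighbor_counts"))
  expect_true(all(mat$x_um >= 0 & mat$x_um <= 5))
  # a regular 2x2 grid with 0.4 um spacing: every point sees the other 3
  grid <- expand.grid(x = c(0.3, 0.7), y = c(0.3, 0.7))
  expect_identical(neighbor_counts(as.matrix(grid), window = 1),
                   rep(3L, 4))
  a <- make_point_pattern(n = 40, seed = 9)
  b <- make_point_pattern(n = 40, seed = 9)
  expect_identical(a, b)
})
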