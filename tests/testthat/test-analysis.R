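# Cluster statistics: identification, areas, t_c, modal pattern, dwell
# times, neighbor counts, box-plot summaries and group tests.

test_that("identify_clusters follows the membership and threshold rules", {
  cfg <- default_config()
  # no bonds -> no clusters
  st <- random_initial_state(tiny_config(), seed = 1)
  expect_identical(identify_clusters(st)$n_clusters, 0L)
  # a 30-mer plus a free membrane clathrin, threshold 5 -> one cluster
  st2 <- make_bond_graph(c(30, 1), cfg, seed = 2)
  cf2 <- identify_clusters(st2, min_cluster_size = 5)
  expect_identical(cf2$n_clusters, 1L)
  expect_identical(cf2$cluster_sizes, 30L)
  # two components of 12 and 7
  st3 <- make_bond_graph(c(12, 7), cfg, seed = 3)
  cf3 <- identify_clusters(st3, min_cluster_size = 5)
  expect_identical(sort(cf3$cluster_sizes), c(7L, 12L))
  expect_identical(cf3$n_membrane_clathrin, 19L)
})

test_that("identify_clusters agrees with a BFS oracle on 1000 random graphs", {
  set.seed(101)
  for (i in 1:1000) {
    n <- sample(5:40, 1)
    min_size <- sample(1:6, 1)
    st <- random_bond_state(n)
    cf <- identify_clusters(st, min_cluster_size = min_size)
    expect_identical(sort(cf$cluster_sizes), oracle_cluster_sizes(st, min_size))
  }
})

test_that("cluster_area matches the dilated-hull formulas", {
  expect_equal(cluster_area(matrix(c(0, 0), 1), pad = 5), pi * 25)
  sq <- rbind(c(0, 0), c(100, 0), c(100, 100), c(0, 100))
  expect_equal(cluster_area(sq, pad = 0), 1e4)       # nm^2 = 0.01 um^2 scaled
  expect_equal(cluster_area(sq, pad = 5), 1e4 + 400 * 5 + pi * 25)
  # collinear pair: dilated segment
  expect_equal(cluster_area(rbind(c(0, 0), c(60, 0)), pad = 5),
               2 * 60 * 5 + pi * 25)
  set.seed(5)
  for (i in 1:50) {
    pts <- matrix(runif(2 * sample(5:60, 1), 0, 200), ncol = 2)
    expect_equal(cluster_area(pts, pad = 0), oracle_hull_area(pts),
                 tolerance = 1e-9)
  }
})

test_that("compute_tc finds the 90% crossing", {
  times <- seq(0, 1800, by = 18)           # 30 min sampled at 18 s
  counts <- seq(0, 100, length.out = length(times))
  expect_equal(compute_tc(times, counts), 1620)   # 27 min
  expect_equal(compute_tc(c(0, 1, 2), c(50, 50, 50)), 0)
  expect_equal(compute_tc(c(5, 6, 7), c(7, 3, 0)), 0)
  expect_error(compute_tc(numeric(0), numeric(0)), "empty")
})

test_that("most_possible_pattern takes the modal value, ties to the smaller", {
  r <- most_possible_pattern(c(2, 2, 1, 2, 2))
  expect_identical(r$mode, 2L)
  expect_equal(as.numeric(r$frequency[c("1", "2")]), c(0.2, 0.8))
  expect_identical(most_possible_pattern(rep(7L, 10))$mode, 7L)
  expect_identical(most_possible_pattern(c(1, 1, 3, 3))$mode, 1L)
  set.seed(6)
  series <- sample(1:3, 1e4, replace = TRUE, prob = c(0.3, 0.6, 0.1))
  expect_identical(most_possible_pattern(series)$mode, 2L)
})

test_that("dwell_segments run-length encodes with boundary censoring", {
  segs <- dwell_segments(c(1, 1, 1, 2, 2), 0.1)
  expect_equal(segs$value, c(1, 2))
  expect_equal(segs$duration_s, c(0.3, 0.2))
  expect_true(all(segs$censored))
  one <- dwell_segments(rep(4L, 20), 0.5)
  expect_identical(nrow(one), 1L)
  expect_true(one$censored)
  expect_equal(one$duration_s, 10)
})

test_that("summarize_trajectory reproduces the hand-worked fixture exactly", {
  frames <- read.csv(system.file("extdata", "hand_frames.csv", package = "fclsim"))
  m <- summarize_trajectory(frames)
  # by hand: end count 100, 90% first reached at t = 2 -> t_c = 2;
  # post-t_c cluster numbers [2,1,2,2,1]: mode 2 (freq 3/5);
  # modal frames' mean sizes 0.060/2, 0.050/2, 0.070/2 -> mean 0.03;
  # dwell runs 2|1|22|1 -> only the interior [2,2] run is uncensored -> 2 s
  expect_identical(m$t_c_s, 2)
  expect_identical(m$modal_cluster_number, 2L)
  expect_equal(m$mean_mean_cluster_size_um2, 0.03)
  expect_equal(m$mean_dwelling_time_s, 2)
  expect_identical(m$n_frames_post_tc, 5L)
  expect_equal(as.numeric(m$histograms$cluster_number[c("1", "2")]),
               c(0.4, 0.6))
  expect_equal(sort(m$histograms$mean_size_um2), c(0.025, 0.030, 0.035))
})

test_that("summarize_trajectory is invariant to frame over-sampling", {
  frames <- read.csv(system.file("extdata", "hand_frames.csv", package = "fclsim"))
  # double the frame rate of the piecewise-constant series
  dense <- frames[rep(seq_len(nrow(frames)), each = 2), ]
  dense$time_s <- dense$time_s + rep(c(0, 0.5), nrow(frames))
  m1 <- summarize_trajectory(frames)
  m2 <- summarize_trajectory(dense)
  expect_identical(m2$modal_cluster_number, m1$modal_cluster_number)
  expect_equal(m2$mean_mean_cluster_size_um2, m1$mean_mean_cluster_size_um2)
  expect_equal(m2$mean_dwelling_time_s, m1$mean_dwelling_time_s)
  expect_equal(m2$t_c_s, m1$t_c_s)
})

test_that("degenerate summaries error informatively", {
  expect_error(summarize_trajectory(data.frame(time_s = 1)), "missing frame columns")
})

test_that("neighbor_counts matches its definition and the O(n^2) oracle", {
  expect_identical(neighbor_counts(matrix(c(0.5, 0.5), 1)), 0L)
  two <- rbind(c(0.1, 0.5), c(0.5, 0.5))       # 0.4 um apart on one axis
  expect_identical(neighbor_counts(two, window = 1), c(1L, 1L))
  far <- rbind(c(0, 0), c(0.6, 0))             # outside the half-window
  expect_identical(neighbor_counts(far, window = 1), c(0L, 0L))
  set.seed(9)
  for (i in 1:50) {
    xy <- matrix(runif(2 * sample(2:50, 1), 0, 3), ncol = 2)
    w <- runif(1, 0.3, 1.5)
    expect_identical(neighbor_counts(xy, w), oracle_neighbor_counts(xy, w))
  }
})

test_that("area_stats uses type-7 quartiles and Tukey fences", {
  one <- area_stats(1)
  expect_true(all(unlist(one[c("median", "q25", "q75", "whisker_low",
                               "whisker_high")]) == 1))
  s <- area_stats(1:9)
  expect_equal(s$median, 5)
  expect_equal(s$q25, 3)        # type-7 linear interpolation on 1..9
  expect_equal(s$q75, 7)
  expect_identical(length(s$outliers), 0L)
  with_out <- area_stats(c(1:10, 100))
  expect_equal(with_out$outliers, 100)
  expect_equal(with_out$whisker_high, 10)
  # permutation invariance
  set.seed(4)
  x <- rlnorm(40)
  expect_equal(area_stats(x), area_stats(sample(x)))
})

test_that("compare_groups is an unpaired t-test with the expected symmetry", {
  same <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  a <- c(1, 2, 3); b <- a + 10
  r <- compare_groups(a, b)
  # textbook Welch statistic: equal variances s^2 = 1, n = 3
  expect_equal(r$statistic, -10 / sqrt(1 / 3 + 1 / 3))
  r2 <- compare_groups(b, a)
  expect_equal(r2$statistic, -r$statistic)
  expect_equal(r2$p_value, r$p_value)
  expect_error(compare_groups(c(1, 1), c(2, 2)), "zero variance")
  expect_error(compare_groups(1, c(1, 2)), "at least 2")
})
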