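# Synthetic-data generators with analytic ground truth, so every analysis
# operation is testable without running the simulator.  Ground-truth
# fields are computed from the generating process (or embedded brute
# force), never by the code under test.

#' Synthetic cluster-number trace with known statistics
#'
#' Simulates a Markov chain over cluster numbers `0..K` (given by the
#' transition matrix) and draws per-cluster areas from a per-state
#' lognormal, emulating the statistical structure of a cluster-dynamics
#' time series. Returns the frame table consumed by
#' [summarize_trajectory()] together with the exact stationary mode,
#' expected dwelling times (geometric-run closed form
#' `frame_interval / (1 - p_self)`), and expected mean cluster areas
#' (`exp(mu + sigma^2/2)`).
#'
#' @param transition Square stochastic matrix; state `i` corresponds to
#'   cluster number `i - 1`.
#' @param n_frames Number of frames.
#' @param frame_interval Frame spacing, s.
#' @param area_meanlog,area_sdlog Lognormal parameters of a single
#'   cluster's area (um^2); scalars or one value per state.
#' @param n_membrane Constant membrane-clathrin count written to the
#'   frame table (keeps t_c at the first frame).
#' @param seed Optional seed.
#' @return A list: `frames` (data frame with `time_s`,
#'   `n_membrane_clathrin`, `n_clusters`, `total_area_um2`), `series`,
#'   and `ground_truth` (list with `stationary`, `mode`,
#'   `mean_dwell_s` per state, `mean_area_um2` per state).
#' @export
make_cluster_trace <- function(transition, n_frames = 1e4, frame_interval = 0.1,
                               area_meanlog = log(0.03), area_sdlog = 0.25,
                               n_membrane = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  P <- as.matrix(transition)
  K <- nrow(P)
  if (ncol(P) != K) stop("transition matrix must be square")
  if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-8))
    stop("transition matrix rows must be non-negative and sum to 1")
  mlog <- rep_len(area_meanlog, K)
  slog <- rep_len(area_sdlog, K)
  # stationary distribution: left eigenvector for eigenvalue 1
  ev <- eigen(t(P))
  i1 <- which.min(abs(ev$values - 1))
  stat <- Re(ev$vectors[, i1])
  stat <- stat / sum(stat)
  states <- integer(n_frames)
  s <- which.max(stat)
  for (f in seq_len(n_frames)) {
    states[f] <- s
    s <- sample.int(K, 1, prob = P[s, ])
  }
  n_clusters <- states - 1L
  total_area <- vapply(seq_len(n_frames), function(f) {
    k <- n_clusters[f]
    if (k == 0) 0 else sum(stats::rlnorm(k, mlog[states[f]], slog[states[f]]))
  }, numeric(1))
  frames <- data.frame(time_s = (seq_len(n_frames) - 1) * frame_interval,
                       n_membrane_clathrin = n_membrane,
                       n_clusters = n_clusters,
                       total_area_um2 = total_area)
  ground_truth <- list(
    stationary = stat,
    mode = which.max(stat) - 1L,
    mean_dwell_s = frame_interval / (1 - diag(P)),
    mean_area_um2 = exp(mlog + slog^2 / 2))
  list(frames = frames, series = n_clusters, ground_truth = ground_truth)
}

#' Synthetic planar bond-graph fixture
#'
#' Builds connected honeycomb components of the requested sizes, with
#' geometrically exact bonds (bound sites 5 nm apart) on the membrane
#' plane, anchored by one AP-2 each, at well-separated positions.
#'
#' @param size_list Integer vector of component sizes (>= 1 each).
#' @param config Configuration (box and site geometry).
#' @param seed Optional seed.
#' @return An `fcl_state` whose clusters are exactly the requested
#'   components, with attribute `"sizes"` carrying the ground truth.
#' @export
make_bond_graph <- function(size_list, config = default_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(size_list < 1)) stop("component sizes must be >= 1")
  config <- validate_config(config)
  geom <- do.call(site_geometry, config$site_geometry)
  L <- config$box$edge_length_um * 1e3
  k <- length(size_list)
  grid <- ceiling(sqrt(k))
  cell <- L / grid
  pos <- NULL; quat <- NULL
  leg_bond <- NULL; leg_bond_site <- NULL
  ap2_bond <- integer(0)
  ap2_pos <- NULL; ap2_partner <- integer(0)
  offset <- 0L
  for (ci in seq_along(size_list)) {
    n <- size_list[ci]
    cx <- (((ci - 1) %% grid) + 0.5) * cell
    cy <- ((ci - 1) %/% grid + 0.5) * cell
    patch <- honeycomb_patch(n, geom, center_xy = c(cx, cy))
    pos <- rbind(pos, cbind(patch$xy, geom$ap2_arm_length_nm))
    quat <- rbind(quat, t(vapply(patch$angle, quat_about_z, numeric(4))))
    lb <- patch$leg_bond
    lb[lb > 0] <- lb[lb > 0] + offset
    leg_bond <- rbind(leg_bond, lb)
    leg_bond_site <- rbind(leg_bond_site, patch$leg_bond_site)
    # anchor the first member of each component
    ap2_pos <- rbind(ap2_pos, patch$xy[1, ])
    ap2_bond <- c(ap2_bond, c(length(ap2_partner) + 1L, rep(0L, n - 1)))
    ap2_partner <- c(ap2_partner, offset + 1L)
    offset <- offset + n
  }
  st <- sim_state(pos, quat, rep(1L, offset), ap2_pos,
                  leg_bond, leg_bond_site, ap2_bond, ap2_partner)
  attr(st, "sizes") <- as.integer(size_list)
  st
}

#' Synthetic spatial point pattern with ground-truth neighbor counts
#'
#' Uniform or Matern-clustered centroids in a square window with
#' lognormal areas; brute-force neighbor counts (O(n^2) double loop) are
#' embedded as ground truth.
#'
#' @param n Number of points (for `"uniform"`), or expected number for
#'   the clustered mode.
#' @param domain_um Square side, um.
#' @param placement `"uniform"` or `"matern"`.
#' @param n_parents,cluster_radius_um Matern parameters.
#' @param area_meanlog,area_sdlog Lognormal area parameters (um^2).
#' @param window_um Neighbor-count window side, um.
#' @param seed Optional seed.
#' @return A data frame (`x_um`, `y_um`, `area_um2`) with attribute
#'   `"neighbor_counts"` (brute force) and `"window_um"`.
#' @export
make_point_pattern <- function(n = 50, domain_um = 5,
                               placement = c("uniform", "matern"),
                               n_parents = 5, cluster_radius_um = 0.3,
                               area_meanlog = log(0.05), area_sdlog = 0.5,
                               window_um = 1, seed = NULL) {
  placement <- match.arg(placement)
  if (!is.null(seed)) set.seed(seed)
  if (placement == "uniform") {
    xy <- matrix(stats::runif(2 * n, 0, domain_um), n, 2)
  } else {
    parents <- matrix(stats::runif(2 * n_parents, 0, domain_um), n_parents, 2)
    per <- stats::rmultinom(1, n, rep(1 / n_parents, n_parents))[, 1]
    xy <- do.call(rbind, lapply(seq_len(n_parents), function(p) {
      if (per[p] == 0) return(NULL)
      r <- cluster_radius_um * sqrt(stats::runif(per[p]))
      th <- stats::runif(per[p], 0, 2 * pi)
      cbind(parents[p, 1] + r * cos(th), parents[p, 2] + r * sin(th))
    }))
    xy[, 1] <- pmin(pmax(xy[, 1], 0), domain_um)
    xy[, 2] <- pmin(pmax(xy[, 2], 0), domain_um)
  }
  n <- nrow(xy)
  # embedded brute-force double loop (the oracle, not the code under test)
  half <- window_um / 2
  counts <- integer(n)
  for (i in seq_len(n)) {
    ci <- 0L
    for (j in seq_len(n)) {
      if (i == j) next
      if (abs(xy[j, 1] - xy[i, 1]) <= half && abs(xy[j, 2] - xy[i, 2]) <= half)
        ci <- ci + 1L
    }
    counts[i] <- ci
  }
  out <- data.frame(x_um = xy[, 1], y_um = xy[, 2],
                    area_um2 = stats::rlnorm(n, area_meanlog, area_sdlog))
  attr(out, "neighbor_counts") <- counts
  attr(out, "window_um") <- window_um
  out
}
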