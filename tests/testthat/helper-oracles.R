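# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: the hull oracle is an O(n^3) half-plane test,
# the component oracle a plain BFS, the neighbor oracle a double loop.

# convex hull area by brute force: a directed pair (i, j) is a hull edge
# iff every other point lies on its left; vertices are ordered by angle
# about the centroid before the shoelace sum.
oracle_hull_area <- function(xy) {
  xy <- unique(rbind(xy))
  n <- nrow(xy)
  if (n < 3) return(0)
  on_hull <- rep(FALSE, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    v <- xy[j, ] - xy[i, ]
    others <- xy[-c(i, j), , drop = FALSE]
    cr <- v[1] * (others[, 2] - xy[i, 2]) - v[2] * (others[, 1] - xy[i, 1])
    if (all(cr >= -1e-12)) on_hull[c(i, j)] <- TRUE
  }
  h <- xy[on_hull, , drop = FALSE]
  ctr <- colMeans(h)
  h <- h[order(atan2(h[, 2] - ctr[2], h[, 1] - ctr[1])), , drop = FALSE]
  k <- nrow(h)
  j <- c(2:k, 1)
  abs(sum(h[, 1] * h[j, 2] - h[j, 1] * h[, 2])) / 2
}

# connected components of a leg-bond matrix by BFS
oracle_components <- function(leg_bond) {
  n <- nrow(leg_bond)
  adj <- lapply(seq_len(n), function(i) leg_bond[i, leg_bond[i, ] > 0])
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, adj[[v]][is.na(comp[adj[[v]]])])
    }
  }
  comp
}

# cluster counting rule applied on top of the BFS oracle
oracle_cluster_sizes <- function(state, min_size) {
  comp <- oracle_components(state$clat$leg_bond)
  mem <- state$clat$comp == 1
  sizes <- integer(0)
  for (cid in unique(comp)) {
    members <- which(comp == cid & mem)
    anchored <- any(state$clat$ap2_bond[comp == cid] > 0)
    if (length(members) >= min_size && anchored)
      sizes <- c(sizes, length(members))
  }
  sort(sizes)
}

oracle_neighbor_counts <- function(xy, window) {
  n <- nrow(xy)
  half <- window / 2
  out <- integer(n)
  for (i in seq_len(n)) {
    ci <- 0L
    for (j in seq_len(n)) {
      if (i == j) next
      if (abs(xy[j, 1] - xy[i, 1]) <= half && abs(xy[j, 2] - xy[i, 2]) <= half)
        ci <- ci + 1L
    }
    out[i] <- ci
  }
  out
}

# a random (not geometrically embedded) bond state for cluster-rule tests:
# random leg pairings plus random membrane/anchor flags
random_bond_state <- function(n, n_bond_attempts = n, p_membrane = 0.7,
                              p_anchor = 0.5) {
  leg_bond <- matrix(0L, n, 3)
  leg_bond_site <- matrix(0L, n, 3)
  for (b in seq_len(n_bond_attempts)) {
    i <- sample.int(n, 1)
    j <- sample.int(n, 1)
    if (i == j) next
    ki <- which(leg_bond[i, ] == 0)
    kj <- which(leg_bond[j, ] == 0)
    if (!length(ki) || !length(kj)) next
    if (j %in% leg_bond[i, ]) next
    ki <- ki[1]; kj <- kj[1]
    leg_bond[i, ki] <- j; leg_bond_site[i, ki] <- kj
    leg_bond[j, kj] <- i; leg_bond_site[j, kj] <- ki
  }
  comp <- oracle_components(leg_bond)
  mem_comp <- stats::runif(max(comp)) < p_membrane
  membrane <- as.integer(mem_comp[comp])
  ap2_bond <- integer(n)
  next_ap2 <- 0L
  for (cid in which(mem_comp)) {
    members <- which(comp == cid)
    if (stats::runif(1) < p_anchor) {
      next_ap2 <- next_ap2 + 1L
      ap2_bond[members[1]] <- next_ap2
    }
  }
  m <- max(next_ap2, 1L)
  ap2_partner <- integer(m)
  ap2_partner[ap2_bond[ap2_bond > 0]] <- which(ap2_bond > 0)
  sim_state(matrix(stats::runif(3 * n, 0, 1000), n, 3),
            random_quaternion(n), membrane,
            matrix(stats::runif(2 * m, 0, 1000), m, 2),
            leg_bond, leg_bond_site, ap2_bond, ap2_partner)
}

# small fast configuration for engine tests
tiny_config <- function(...) {
  cfg <- scaled_down_config()
  cfg$copy_numbers$n_clathrin <- 20L
  cfg$copy_numbers$n_ap2 <- 10L
  over <- list(...)
  for (nm in names(over)) {
    parts <- strsplit(nm, "\\.")[[1]]
    cfg[[parts[1]]][[parts[2]]] <- over[[nm]]
  }
  cfg
}

# state of n_pairs isolated bonded cytosolic dimers on a 3D grid inside a
# cube large enough to keep them independent; no AP-2 (m = 1 free AP-2 to
# satisfy the container, placed far away is not needed since rates are 0)
dimer_field_state <- function(n_pairs, spacing_nm = 150) {
  geom <- site_geometry()
  per_axis <- ceiling(n_pairs^(1 / 3))
  L <- (per_axis + 1) * spacing_nm
  pos <- matrix(0, n_pairs * 2, 3)
  quat <- matrix(rep(c(1, 0, 0, 0), n_pairs * 2), ncol = 4, byrow = TRUE)
  leg_bond <- matrix(0L, n_pairs * 2, 3)
  leg_bond_site <- matrix(0L, n_pairs * 2, 3)
  idx <- 0
  for (p in seq_len(n_pairs)) {
    gx <- (p - 1) %% per_axis
    gy <- ((p - 1) %/% per_axis) %% per_axis
    gz <- (p - 1) %/% (per_axis^2)
    base <- c(gx, gy, gz) * spacing_nm + spacing_nm / 2
    a <- idx + 1L; b <- idx + 2L
    pos[a, ] <- base
    # partner head-to-head on leg 1 (+x): distance 2*leg + bond, rotated 180
    # about z so its leg 1 points back
    pos[b, ] <- base + c(2 * geom$leg_length_nm + geom$bond_length_nm, 0, 0)
    quat[b, ] <- c(0, 0, 0, 1)
    leg_bond[a, 1] <- b; leg_bond_site[a, 1] <- 1L
    leg_bond[b, 1] <- a; leg_bond_site[b, 1] <- 1L
    idx <- idx + 2L
  }
  st <- sim_state(pos, quat, integer(n_pairs * 2),
                  matrix(c(L / 2, L / 2), 1, 2),
                  leg_bond, leg_bond_site)
  attr(st, "edge_um") <- L / 1e3
  st
}

# configuration for pure-dissociation experiments on a dimer field
dissociation_config <- function(edge_um, k_off, dt) {
  cfg <- default_config()
  cfg$box$edge_length_um <- edge_um
  cfg$copy_numbers$n_clathrin <- 0L
  cfg$copy_numbers$n_ap2 <- 0L
  cfg$kinetics$k_clat_clat_on_uM_s <- 0
  cfg$kinetics$k_clat_ap2_on_uM_s <- 0
  cfg$kinetics$k_clat_clat_off_s <- k_off
  cfg$kinetics$k_clat_ap2_off_s <- 0
  cfg$kinetics$d_clat_trans_um2_s <- 0
  cfg$kinetics$d_clat_rot_s <- 0
  cfg$kinetics$d_ap2_trans_um2_s <- 0
  cfg$kinetics$dt_s <- dt
  cfg
}
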