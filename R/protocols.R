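# Reproducible experiment drivers: initial conditions, parameter sweeps
# with replicates, growth-factor stimulus schedules, and the well-mixed
# A+B <-> AB validation harness.

#' Random initial state
#'
#' Clathrins are placed uniformly in the box with uniform random
#' orientations and no overlaps (rejection sampling); AP-2s uniformly on
#' the membrane; no bonds.
#'
#' @param config Configuration list.
#' @param seed Optional integer seed.
#' @return An `fcl_state`.
#' @export
random_initial_state <- function(config = default_config(), seed = NULL) {
  config <- validate_config(config)
  if (!is.null(seed)) set.seed(seed)
  L <- config$box$edge_length_um * 1e3
  n <- config$copy_numbers$n_clathrin
  m <- config$copy_numbers$n_ap2
  rmin2 <- (2 * config$site_geometry$excluded_volume_radius_nm)^2
  pos <- matrix(NA_real_, n, 3)
  placed <- 0
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(1000)) {
      p <- stats::runif(3, 0, L)
      if (placed == 0 ||
          min(colSums((t(pos[seq_len(placed), , drop = FALSE]) - p)^2)) >= rmin2) {
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not place clathrin ", i, " without overlap")
    pos[i, ] <- p
    placed <- i
  }
  quat <- random_quaternion(max(n, 1))[seq_len(n), , drop = FALSE]
  ap2 <- matrix(stats::runif(2 * m, 0, L), m, 2)
  sim_state(pos, quat, integer(n), ap2)
}

# honeycomb lattice of n bonded clathrins centered at `center_xy` (nm).
# Sublattice A molecules point their legs at 0/120/240 degrees, sublattice
# B at 60/180/300; neighbor spacing is 2*leg + bond so every bond is exact.
honeycomb_patch <- function(n, geom, center_xy = c(0, 0)) {
  a <- 2 * geom$leg_length_nm + geom$bond_length_nm
  ang_A <- c(0, 120, 240) * pi / 180
  ang_B <- c(60, 180, 300) * pi / 180
  key <- function(p) paste(round(p[1], 3), round(p[2], 3))
  nodes <- list(list(p = c(0, 0), type = 0L))
  names(nodes) <- key(c(0, 0))
  sel <- list()
  queue <- list(nodes[[1]])
  while (length(sel) < n && length(queue)) {
    nd <- queue[[1]]
    queue <- queue[-1]
    k <- key(nd$p)
    if (!is.null(sel[[k]])) next
    sel[[k]] <- nd
    angs <- if (nd$type == 0L) ang_A else ang_B
    for (th in angs) {
      np <- nd$p + a * c(cos(th), sin(th))
      nk <- key(np)
      if (is.null(sel[[nk]]))
        queue[[length(queue) + 1]] <- list(p = np, type = 1L - nd$type)
    }
  }
  if (length(sel) < n) stop("could not grow a honeycomb patch of size ", n)
  pts <- do.call(rbind, lapply(sel, `[[`, "p"))
  type <- vapply(sel, `[[`, integer(1), "type")
  off <- center_xy - colMeans(pts)
  pts <- sweep(pts, 2, -off)
  leg_bond <- matrix(0L, n, 3)
  leg_bond_site <- matrix(0L, n, 3)
  for (i in seq_len(n)) {
    angs_i <- if (type[i] == 0L) ang_A else ang_B
    for (k in 1:3) {
      tgt <- pts[i, ] + a * c(cos(angs_i[k]), sin(angs_i[k]))
      d2 <- (pts[, 1] - tgt[1])^2 + (pts[, 2] - tgt[2])^2
      j <- which(d2 < 1e-4)
      if (length(j) == 1) {
        angs_j <- if (type[j] == 0L) ang_A else ang_B
        back <- (angs_i[k] + pi) %% (2 * pi)
        kj <- which(abs(((angs_j - back + pi) %% (2 * pi)) - pi) < 1e-6)
        leg_bond[i, k] <- j
        leg_bond_site[i, k] <- kj
      }
    }
  }
  list(xy = pts, angle = ifelse(type == 0L, 0, pi / 3),
       leg_bond = leg_bond, leg_bond_site = leg_bond_site)
}

#' Single-cluster initial state
#'
#' One connected, fully bonded flat honeycomb patch of
#' `n_clathrin_in_cluster` membrane clathrins at the box center, each
#' anchored by its own AP-2 (up to the available AP-2 count); the
#' remaining clathrins are placed randomly in the cytosol and the
#' remaining AP-2s randomly on the membrane.
#'
#' @param config Configuration list.
#' @param n_clathrin_in_cluster Patch size (<= total clathrin count).
#' @param seed Optional integer seed.
#' @return An `fcl_state`.
#' @export
single_cluster_initial_state <- function(config = default_config(),
                                         n_clathrin_in_cluster = 19,
                                         seed = NULL) {
  config <- validate_config(config)
  if (!is.null(seed)) set.seed(seed)
  nc <- n_clathrin_in_cluster
  n <- config$copy_numbers$n_clathrin
  m <- config$copy_numbers$n_ap2
  if (nc > n) stop("cluster size exceeds the clathrin copy number")
  L <- config$box$edge_length_um * 1e3
  geom <- do.call(site_geometry, config$site_geometry)
  patch <- honeycomb_patch(nc, geom, center_xy = c(L / 2, L / 2))
  if (any(patch$xy < 0) || any(patch$xy > L))
    stop("honeycomb patch does not fit in the box")
  h <- geom$ap2_arm_length_nm
  pos <- cbind(patch$xy, rep(h, nc))
  quat <- t(vapply(patch$angle, quat_about_z, numeric(4)))
  comp <- rep(1L, nc)
  leg_bond <- patch$leg_bond
  leg_bond_site <- patch$leg_bond_site
  n_anchor <- min(nc, m)
  ap2_bond <- c(seq_len(n_anchor), rep(0L, nc - n_anchor))
  ap2_pos <- patch$xy[seq_len(n_anchor), , drop = FALSE]
  ap2_partner <- seq_len(n_anchor)
  # free AP-2s
  if (m > n_anchor)
    ap2_pos <- rbind(ap2_pos, matrix(stats::runif(2 * (m - n_anchor), 0, L),
                                     m - n_anchor, 2))
  ap2_partner <- c(ap2_partner, rep(0L, m - n_anchor))
  # cytosolic remainder
  rmin2 <- (2 * geom$excluded_volume_radius_nm)^2
  extra <- n - nc
  if (extra > 0) {
    for (i in seq_len(extra)) {
      ok <- FALSE
      for (try in seq_len(1000)) {
        p <- stats::runif(3, 0, L)
        if (min(colSums((t(pos) - p)^2)) >= rmin2) {
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("could not place cytosolic clathrin without overlap")
      pos <- rbind(pos, p)
    }
    quat <- rbind(quat, random_quaternion(extra))
    comp <- c(comp, rep(0L, extra))
    leg_bond <- rbind(leg_bond, matrix(0L, extra, 3))
    leg_bond_site <- rbind(leg_bond_site, matrix(0L, extra, 3))
    ap2_bond <- c(ap2_bond, rep(0L, extra))
  }
  sim_state(pos, quat, comp, ap2_pos, leg_bond, leg_bond_site,
            ap2_bond, ap2_partner)
}

#' Parameter sweep specification
#'
#' @param variable One of `"ap2_number"`, `"k_clat_clat_fold"`,
#'   `"d_clat_fold"`.
#' @param values Numeric vector of values (copy numbers or fold factors).
#' @param replicates Replicates per value (default 4).
#' @param base_config Baseline configuration.
#' @param seeds Integer vector, one per run
#'   (`length(values) * replicates`); defaults to `seq_len`.
#' @param duration Simulated seconds per run.
#' @param frame_interval Snapshot spacing, s.
#' @return A list of class `fcl_sweep_spec`.
#' @export
sweep_spec <- function(variable = c("ap2_number", "k_clat_clat_fold", "d_clat_fold"),
                       values, replicates = 4, base_config = scaled_down_config(),
                       seeds = NULL, duration = 20, frame_interval = 0.1) {
  variable <- match.arg(variable)
  n_runs <- length(values) * replicates
  if (is.null(seeds)) seeds <- seq_len(n_runs)
  if (length(seeds) != n_runs)
    stop("need length(values) * replicates seeds")
  if (variable != "ap2_number" && any(values <= 0))
    stop("fold factors must be > 0")
  structure(list(variable = variable, values = values, replicates = replicates,
                 base_config = validate_config(base_config), seeds = seeds,
                 duration = duration, frame_interval = frame_interval),
            class = "fcl_sweep_spec")
}

sweep_config <- function(spec, value) {
  cfg <- spec$base_config
  switch(spec$variable,
         ap2_number = { cfg$copy_numbers$n_ap2 <- as.integer(value) },
         k_clat_clat_fold = {
           cfg$kinetics$k_clat_clat_on_uM_s <- cfg$kinetics$k_clat_clat_on_uM_s * value
         },
         d_clat_fold = {
           cfg$kinetics$d_clat_trans_um2_s <- cfg$kinetics$d_clat_trans_um2_s * value
         })
  cfg
}

#' Run a parameter sweep
#'
#' For each (value, replicate) pair, simulates from a fresh random initial
#' state and summarizes the trajectory; reports per-run metrics, group
#' mean +/- SD, and unpaired t-tests between consecutive values for each
#' metric.
#'
#' @param spec An [sweep_spec()].
#' @param quiet Suppress per-run progress messages.
#' @return A list of class `fcl_sweep`: `runs`, `groups`, `tests` data
#'   frames.
#' @export
run_sweep <- function(spec, quiet = TRUE) {
  stopifnot(inherits(spec, "fcl_sweep_spec"))
  rows <- list()
  idx <- 0
  for (v in spec$values) {
    cfg <- sweep_config(spec, v)
    for (r in seq_len(spec$replicates)) {
      idx <- idx + 1
      seed <- spec$seeds[idx]
      if (!quiet) message(spec$variable, " = ", v, " replicate ", r)
      st <- random_initial_state(cfg, seed = seed)
      traj <- sim_run(st, cfg, duration = spec$duration,
                      frame_interval = spec$frame_interval)
      m <- summarize_trajectory(traj)
      rows[[idx]] <- data.frame(
        variable = spec$variable, value = v, replicate = r, seed = seed,
        t_c_s = m$t_c_s, modal_cluster_number = m$modal_cluster_number,
        mean_mean_cluster_size_um2 = m$mean_mean_cluster_size_um2,
        mean_dwelling_time_s = m$mean_dwelling_time_s)
    }
  }
  runs <- do.call(rbind, rows)
  metrics <- c("modal_cluster_number", "mean_mean_cluster_size_um2",
               "mean_dwelling_time_s")
  groups <- do.call(rbind, lapply(split(runs, runs$value), function(g) {
    out <- data.frame(value = g$value[1])
    for (mm in metrics) {
      out[[paste0(mm, "_mean")]] <- mean(g[[mm]], na.rm = TRUE)
      out[[paste0(mm, "_sd")]] <- stats::sd(g[[mm]], na.rm = TRUE)
    }
    out
  }))
  groups <- groups[order(groups$value), , drop = FALSE]
  vals <- sort(unique(runs$value))
  tests <- list()
  if (length(vals) > 1) {
    for (i in seq_len(length(vals) - 1)) {
      ga <- runs[runs$value == vals[i], ]
      gb <- runs[runs$value == vals[i + 1], ]
      for (mm in metrics) {
        a <- ga[[mm]][!is.na(ga[[mm]])]
        b <- gb[[mm]][!is.na(gb[[mm]])]
        p <- if (length(a) > 1 && length(b) > 1 &&
                 (stats::sd(a) > 0 || stats::sd(b) > 0))
          compare_groups(a, b)$p_value else NA_real_
        tests[[length(tests) + 1]] <- data.frame(
          metric = mm, value_a = vals[i], value_b = vals[i + 1], p_value = p)
      }
    }
  }
  structure(list(runs = runs, groups = groups,
                 tests = do.call(rbind, tests), spec = spec),
            class = "fcl_sweep")
}

#' Growth-factor stimulus schedule
#'
#' Piecewise-in-time parameter changes mimicking EGF stimulation: the AP-2
#' copy number ramps from `ap2_start` to `ap2_peak` over `[0, t_switch]`,
#' the clathrin-clathrin on-rate is multiplied by `k_fold` and the
#' clathrin diffusion coefficient by `d_fold` (defaults 50 and 1/50); at
#' `t_switch` every parameter reverts to baseline.
#'
#' @param ap2_start,ap2_peak AP-2 copy numbers (defaults 100 and 200).
#' @param k_fold On-rate fold change while stimulated (default 50).
#' @param d_fold Diffusion fold change while stimulated (default 1/50).
#' @param t_switch,t_end Reversal time and run end, s.
#' @param combination Which parameters change: `"ap2_only"`,
#'   `"ap2_plus_k"`, `"ap2_plus_d"`, `"ap2_k_d"`.
#' @param ap2_ramp `"linear"` (default) or `"step"` AP-2 increase.
#' @return A list of class `fcl_egf_schedule`.
#' @export
egf_schedule <- function(ap2_start = 100, ap2_peak = 200, k_fold = 50,
                         d_fold = 1 / 50, t_switch = 30 * 60, t_end = 60 * 60,
                         combination = c("ap2_k_d", "ap2_only", "ap2_plus_k",
                                         "ap2_plus_d"),
                         ap2_ramp = c("linear", "step")) {
  combination <- match.arg(combination)
  ap2_ramp <- match.arg(ap2_ramp)
  if (!(t_switch > 0 && t_switch < t_end))
    stop("need 0 < t_switch < t_end")
  structure(list(ap2_start = ap2_start, ap2_peak = ap2_peak, k_fold = k_fold,
                 d_fold = d_fold, t_switch = t_switch, t_end = t_end,
                 combination = combination, ap2_ramp = ap2_ramp),
            class = "fcl_egf_schedule")
}

#' Scheduled parameter values at a time point
#'
#' @param schedule An [egf_schedule()].
#' @param t Time, s.
#' @return A list: `ap2_target` (copy number), `k_fold`, `d_fold`.
#' @export
apply_schedule <- function(schedule, t) {
  s <- schedule
  if (t >= s$t_switch)
    return(list(ap2_target = as.integer(s$ap2_start), k_fold = 1, d_fold = 1))
  with_k <- s$combination %in% c("ap2_plus_k", "ap2_k_d")
  with_d <- s$combination %in% c("ap2_plus_d", "ap2_k_d")
  ap2 <- if (s$ap2_ramp == "step") s$ap2_peak
         else s$ap2_start + (s$ap2_peak - s$ap2_start) * t / s$t_switch
  list(ap2_target = as.integer(round(ap2)),
       k_fold = if (with_k) s$k_fold else 1,
       d_fold = if (with_d) s$d_fold else 1)
}

# insert or remove AP-2s to reach `target`; removals take free AP-2 first,
# then force-unbind randomly chosen bound ones.  Returns list(state, forced).
adjust_ap2_count <- function(state, target, L_nm) {
  m <- nrow(state$ap2$pos)
  forced <- 0L
  if (target > m) {
    add <- target - m
    state$ap2$pos <- rbind(state$ap2$pos,
                           matrix(stats::runif(2 * add, 0, L_nm), add, 2))
    state$ap2$bond <- c(state$ap2$bond, rep(0L, add))
  } else if (target < m) {
    drop_n <- m - target
    free <- which(state$ap2$bond == 0)
    drop <- head(free[sample.int(length(free))], min(length(free), drop_n))
    if (length(drop) < drop_n) {
      bound <- setdiff(seq_len(m), c(free))
      extra <- sample(bound, drop_n - length(drop))
      forced <- length(extra)
      for (a in extra) {            # force-unbind
        i <- state$ap2$bond[a]
        state$clat$ap2_bond[i] <- 0L
        state$ap2$bond[a] <- 0L
      }
      drop <- c(drop, extra)
    }
    keep <- setdiff(seq_len(m), drop)
    remap <- integer(m)
    remap[keep] <- seq_along(keep)
    state$ap2$pos <- state$ap2$pos[keep, , drop = FALSE]
    state$ap2$bond <- state$ap2$bond[keep]
    b <- state$clat$ap2_bond
    state$clat$ap2_bond <- ifelse(b > 0, remap[pmax(b, 1L)], 0L)
    # a clathrin component losing its last anchor falls back to the cytosol
    comp_id <- bond_components(state$clat$leg_bond)
    anch <- tapply(state$clat$ap2_bond > 0, comp_id, any)
    state$clat$comp <- as.integer(anch[as.character(comp_id)])
  }
  list(state = state, forced = forced)
}

#' Growth-factor stimulus experiment
#'
#' Runs replicates from a single-cluster initial state under an
#' [egf_schedule()], updating parameters every `segment` seconds, and
#' reports cluster number and maximum cluster area over time, normalized
#' to their values at t = 0 (fold change), plus the mean +/- SD over
#' replicates.
#'
#' @param config Baseline configuration.
#' @param schedule An [egf_schedule()].
#' @param n_cluster_init Initial patch size (clathrins).
#' @param replicates Number of replicates (default 3).
#' @param seeds Integer vector of per-replicate seeds.
#' @param segment Parameter-update and sampling interval, s.
#' @return A list of class `fcl_egf`: `curves` (per replicate and time),
#'   `summary` (mean/SD of the fold changes), `forced_unbinds`.
#' @export
egf_experiment <- function(config = scaled_down_config(),
                           schedule = egf_schedule(), n_cluster_init = 19,
                           replicates = 3, seeds = seq_len(replicates),
                           segment = 1) {
  config <- validate_config(config)
  stopifnot(length(seeds) == replicates)
  base_k <- config$kinetics$k_clat_clat_on_uM_s
  base_d <- config$kinetics$d_clat_trans_um2_s
  L <- config$box$edge_length_um * 1e3
  geom <- do.call(site_geometry, config$site_geometry)
  min_sz <- config$analysis$min_cluster_size
  pad <- config$analysis$hull_pad_nm
  n_seg <- ceiling(schedule$t_end / segment)
  forced_total <- 0L
  curves <- list()
  for (r in seq_len(replicates)) {
    set.seed(seeds[r])
    cfg0 <- config
    cfg0$copy_numbers$n_ap2 <- as.integer(schedule$ap2_start)
    state <- single_cluster_initial_state(cfg0, n_cluster_init)
    snap <- function(st) {
      cf <- identify_clusters(st, min_sz, geom, pad)
      c(n_clusters = cf$n_clusters,
        max_area = if (cf$n_clusters > 0) max(cf$cluster_areas_um2) else 0)
    }
    s0 <- snap(state)
    rows <- data.frame(time_s = 0, replicate = r,
                       n_clusters = s0["n_clusters"], max_area_um2 = s0["max_area"])
    for (sgi in seq_len(n_seg)) {
      t0 <- (sgi - 1) * segment
      sched <- apply_schedule(schedule, t0)
      cfg <- config
      cfg$kinetics$k_clat_clat_on_uM_s <- base_k * sched$k_fold
      cfg$kinetics$d_clat_trans_um2_s <- base_d * sched$d_fold
      adj <- adjust_ap2_count(state, sched$ap2_target, L)
      state <- adj$state
      forced_total <- forced_total + adj$forced
      state <- sim_step(state, cfg,
                        n_steps = round(segment / cfg$kinetics$dt_s))
      s1 <- snap(state)
      rows <- rbind(rows, data.frame(time_s = sgi * segment, replicate = r,
                                     n_clusters = s1["n_clusters"],
                                     max_area_um2 = s1["max_area"]))
    }
    rows$fold_number <- rows$n_clusters / max(rows$n_clusters[1], 1)
    rows$fold_max_area <- rows$max_area_um2 /
      ifelse(rows$max_area_um2[1] > 0, rows$max_area_um2[1], 1)
    curves[[r]] <- rows
  }
  curves <- do.call(rbind, curves)
  rownames(curves) <- NULL
  summ <- do.call(rbind, lapply(split(curves, curves$time_s), function(g) {
    data.frame(time_s = g$time_s[1],
               fold_number_mean = mean(g$fold_number),
               fold_number_sd = stats::sd(g$fold_number),
               fold_max_area_mean = mean(g$fold_max_area),
               fold_max_area_sd = stats::sd(g$fold_max_area))
  }))
  summ <- summ[order(summ$time_s), , drop = FALSE]
  rownames(summ) <- NULL
  structure(list(curves = curves, summary = summ, schedule = schedule,
                 forced_unbinds = forced_total),
            class = "fcl_egf")
}

#' Well-mixed A+B association/dissociation validation
#'
#' Point particles A and B in a closed box react through the same
#' Doi-acceptance / Poisson-dissociation machinery as the lattice engine.
#' The stationary bound fraction is compared with the mass-action
#' equilibrium root.
#'
#' @param k_on Association rate, 1/(uM s).
#' @param k_off Dissociation rate, 1/s.
#' @param nA,nB Copy numbers.
#' @param box_um Cube edge, um.
#' @param duration Simulated seconds.
#' @param dt Timestep, s.
#' @param sigma_nm Reaction radius, nm.
#' @param D_um2_s Diffusion coefficient of each species, um^2/s.
#' @param seed Optional seed.
#' @param burnin_frac Fraction of the trace discarded before averaging.
#' @return A list: `bound_fraction` (time-averaged), `se` (batch-means
#'   Monte-Carlo standard error), `prediction` (mass-action root),
#'   `trace` (bound-count time series).
#' @export
validate_well_mixed <- function(k_on, k_off, nA = 50, nB = 50, box_um = 0.25,
                                duration = 0.5, dt = 1e-6, sigma_nm = 5,
                                D_um2_s = 10, seed = NULL, burnin_frac = 0.25) {
  if (!is.null(seed)) set.seed(seed)
  L <- box_um * 1e3
  V <- L^3
  kvol <- k_on * 1e9 / .AVOGADRO_uM_um3          # nm^3/s
  k_micro <- kvol / (4 / 3 * pi * sigma_nm^3)
  p_bind <- 1 - exp(-k_micro * dt)
  p_off <- dissociation_probability(k_off, dt)
  n_steps <- as.integer(round(duration / dt))
  record_every <- max(1L, n_steps %/% 2000L)
  res <- cpp_well_mixed(nA, nB, L, sigma_nm, p_bind, p_off,
                        D_um2_s * 1e6, D_um2_s * 1e6, dt,
                        n_steps, record_every)
  trace <- res$trace
  keep <- trace[-seq_len(floor(length(trace) * burnin_frac))]
  nb <- min(20, length(keep))
  batches <- split(keep, cut(seq_along(keep), nb, labels = FALSE))
  bm <- vapply(batches, mean, numeric(1)) / min(nA, nB)
  est <- mean(bm)
  se <- stats::sd(bm) / sqrt(length(bm))
  # mass-action root: (nA - x)(nB - x) = (k_off V / kvol) x
  if (kvol == 0) {
    x <- 0
  } else {
    Kc <- k_off * V / kvol
    b <- -(nA + nB + Kc)
    x <- (-b - sqrt(b^2 - 4 * nA * nB)) / 2
  }
  list(bound_fraction = est, se = se,
       prediction = x / min(nA, nB), trace = trace)
}
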