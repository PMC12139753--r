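# The per-timestep engine wrapper.  The sweep order within a step is fixed:
# dissociation first, then association, then diffusion of everything that
# did not react; a molecule takes part in at most one reaction per step.

#' Dissociation probability per timestep
#'
#' The per-step probability that a bond with dissociation rate `k_off`
#' breaks, `1 - exp(-k_off * dt)`, from the Poisson waiting-time law.
#'
#' @param k_off Dissociation rate, 1/s.
#' @param dt Timestep, s.
#' @return Probability in `[0, 1)`.
#' @export
#' @examples
#' dissociation_probability(1, 3e-6)
dissociation_probability <- function(k_off, dt) {
  if (any(k_off < 0)) stop("k_off must be >= 0")
  if (any(dt <= 0)) stop("dt must be > 0")
  1 - exp(-k_off * dt)
}

#' Diffusion coefficient of an assembled cluster
#'
#' A complex of N bound components diffuses as one unit with
#' `D = (sum_i D_i^(-1/n))^(-n)`, `n = 1` for translation and `n = 3`
#' for rotation.
#'
#' @param d Numeric vector of member diffusion coefficients (all > 0).
#' @param mode `"trans"` (n = 1) or `"rot"` (n = 3).
#' @return The cluster coefficient, same units as `d`.
#' @export
#' @examples
#' cluster_diffusion(rep(13, 13))            # 1
#' cluster_diffusion(rep(1, 8), "rot")       # 1 / 512
cluster_diffusion <- function(d, mode = c("trans", "rot")) {
  mode <- match.arg(mode)
  if (!length(d)) stop("empty component list")
  if (any(d <= 0)) stop("all member coefficients must be > 0")
  n <- if (mode == "trans") 1 else 3
  sum(d^(-1 / n))^(-n)
}

#' Construct a simulation state
#'
#' @param clat_pos n x 3 matrix of clathrin centers, nm.
#' @param clat_quat n x 4 matrix of unit quaternions.
#' @param clat_comp Integer vector, 0 = cytosol, 1 = membrane.
#' @param ap2_pos m x 2 matrix of AP-2 membrane positions, nm.
#' @param leg_bond,leg_bond_site n x 3 integer matrices: partner molecule /
#'   partner site per leg (0 = free).
#' @param ap2_bond Integer length n: bound AP-2 index per clathrin (0 = free).
#' @param ap2_partner Integer length m: bound clathrin per AP-2 (0 = free).
#' @param time Simulation time, s.
#' @return A list of class `fcl_state`.
#' @export
sim_state <- function(clat_pos, clat_quat, clat_comp, ap2_pos,
                      leg_bond = NULL, leg_bond_site = NULL,
                      ap2_bond = NULL, ap2_partner = NULL, time = 0) {
  n <- nrow(clat_pos)
  m <- nrow(ap2_pos)
  if (is.null(leg_bond)) leg_bond <- matrix(0L, n, 3)
  if (is.null(leg_bond_site)) leg_bond_site <- matrix(0L, n, 3)
  if (is.null(ap2_bond)) ap2_bond <- integer(n)
  if (is.null(ap2_partner)) ap2_partner <- integer(m)
  stopifnot(nrow(clat_quat) == n, length(clat_comp) == n,
            length(ap2_bond) == n, length(ap2_partner) == m)
  structure(list(
    time = time,
    clat = list(pos = unname(as.matrix(clat_pos)),
                quat = unname(as.matrix(clat_quat)),
                comp = as.integer(clat_comp),
                leg_bond = matrix(as.integer(leg_bond), n, 3),
                leg_bond_site = matrix(as.integer(leg_bond_site), n, 3),
                ap2_bond = as.integer(ap2_bond)),
    ap2 = list(pos = unname(as.matrix(ap2_pos)),
               bond = as.integer(ap2_partner))
  ), class = "fcl_state")
}

n_clathrin <- function(state) nrow(state$clat$pos)
n_ap2 <- function(state) nrow(state$ap2$pos)

#' Advance a state by whole timesteps
#'
#' Runs `n_steps` engine steps (dissociation, association, diffusion, in
#' that order) without recording frames. Use [sim_run()] to record a
#' trajectory.
#'
#' @param state An `fcl_state`.
#' @param config A configuration list (see [default_config()]).
#' @param n_steps Number of timesteps.
#' @return The advanced `fcl_state` (with `events` and counters attached
#'   as attributes).
#' @export
sim_step <- function(state, config = default_config(), n_steps = 1) {
  config <- validate_config(config)
  res <- cpp_run(unclass(state), engine_params(config), as.integer(n_steps), 0L)
  out <- structure(res$state, class = "fcl_state")
  attr(out, "events") <- res$events
  attr(out, "skipped_moves") <- res$skipped_moves
  out
}

#' Run a simulation and record a trajectory
#'
#' Repeatedly steps the engine and snapshots the full state every
#' `frame_interval` seconds (the initial state is frame 1). All randomness
#' comes from R's RNG: call `set.seed()` (or pass `seed`) for
#' reproducibility.
#'
#' @param state Initial `fcl_state` (see [random_initial_state()]).
#' @param config Configuration list.
#' @param duration Simulated time, s.
#' @param frame_interval Snapshot spacing, s (`>= dt`).
#' @param seed Optional integer seed applied before stepping.
#' @return An `fcl_trajectory`: list with `frames` (each an `fcl_state`),
#'   `events` (data frame), `config`, and move-skip counters.
#' @export
sim_run <- function(state, config = default_config(), duration,
                    frame_interval = duration / 100, seed = NULL) {
  config <- validate_config(config)
  if (!is.null(seed)) set.seed(seed)
  dt <- config$kinetics$dt_s
  if (duration <= 0) stop("duration must be > 0")
  if (frame_interval < dt) stop("frame_interval must be >= dt")
  n_steps <- as.integer(round(duration / dt))
  record_every <- max(1L, as.integer(round(frame_interval / dt)))
  res <- cpp_run(unclass(state), engine_params(config), n_steps, record_every)
  frames <- c(list(structure(unclass(state), class = "fcl_state")),
              lapply(res$frames, function(f) structure(f, class = "fcl_state")))
  structure(list(
    frames = frames,
    events = res$events,
    config = config,
    skipped_moves = res$skipped_moves,
    placement_rejects = res$placement_rejects
  ), class = "fcl_trajectory")
}

#' @export
print.fcl_trajectory <- function(x, ...) {
  tmax <- x$frames[[length(x$frames)]]$time
  cat(sprintf("<fcl_trajectory> %d frames over %.3g s, %d clathrin / %d AP-2\n",
              length(x$frames), tmax,
              nrow(x$frames[[1]]$clat$pos), nrow(x$frames[[1]]$ap2$pos)))
  invisible(x)
}

#' @export
print.fcl_state <- function(x, ...) {
  cat(sprintf("<fcl_state> t = %.4g s, %d clathrin (%d membrane), %d AP-2 (%d bound)\n",
              x$time, nrow(x$clat$pos), sum(x$clat$comp == 1),
              nrow(x$ap2$pos), sum(x$ap2$bond > 0)))
  invisible(x)
}

frame_times <- function(traj) vapply(traj$frames, `[[`, numeric(1), "time")
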