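# Engine contracts: dissociation law, cluster diffusion formula, Brownian
# displacement statistics, determinism, and per-frame invariants.

test_that("dissociation_probability matches the Poisson closed form", {
  expect_identical(dissociation_probability(0, 3e-6), 0)
  expect_equal(dissociation_probability(1e9, 1), 1)
  expect_equal(dissociation_probability(1, 3e-6), 1 - exp(-3e-6))
  expect_lt(abs(dissociation_probability(1, 3e-6) - 2.999996e-6), 1e-11)
  expect_error(dissociation_probability(-1, 1e-6))
  expect_error(dissociation_probability(1, 0))
})

test_that("cluster_diffusion implements (sum D^(-1/n))^(-n)", {
  expect_equal(cluster_diffusion(5), 5)
  expect_equal(cluster_diffusion(5, "rot"), 5)
  expect_equal(cluster_diffusion(rep(13, 13)), 1)
  d <- 0.7
  expect_equal(cluster_diffusion(rep(d, 8), "rot"), d / 512)
  set.seed(3)
  for (i in 1:20) {
    d <- runif(sample(1:6, 1), 0.1, 20)
    expect_equal(cluster_diffusion(d, "trans"), sum(1 / d)^-1)
    expect_equal(cluster_diffusion(d, "rot"), sum(d^(-1 / 3))^-3)
  }
  expect_error(cluster_diffusion(numeric(0)))
  expect_error(cluster_diffusion(c(1, 0)))
})

test_that("identical seeds give bit-identical trajectories", {
  cfg <- tiny_config()
  st <- random_initial_state(cfg, seed = 5)
  t1 <- sim_run(st, cfg, duration = 0.06, frame_interval = 0.01, seed = 99)
  t2 <- sim_run(st, cfg, duration = 0.06, frame_interval = 0.01, seed = 99)
  expect_identical(t1$frames, t2$frames)
  expect_identical(t1$events, t2$events)
  t3 <- sim_run(st, cfg, duration = 0.06, frame_interval = 0.01, seed = 100)
  expect_false(identical(t1$frames, t3$frames))
})

test_that("empty and decoupled systems behave trivially", {
  # zero rates, D > 0: pure diffusion, no events
  cfg <- tiny_config()
  cfg$kinetics$k_clat_clat_on_uM_s <- 0
  cfg$kinetics$k_clat_ap2_on_uM_s <- 0
  st <- random_initial_state(cfg, seed = 2)
  traj <- sim_run(st, cfg, duration = 0.03, frame_interval = 0.003, seed = 1)
  expect_identical(nrow(traj$events), 0L)
  last <- traj$frames[[length(traj$frames)]]
  expect_false(identical(last$clat$pos, st$clat$pos))
  expect_true(all(last$clat$leg_bond == 0))
  # D = 0 and no rates: nothing moves at all
  cfg0 <- dissociation_config(attr(dimer_field_state(4), "edge_um"), 0, 1e-4)
  st0 <- dimer_field_state(4)
  out <- sim_step(st0, cfg0, n_steps = 50)
  expect_equal(out$clat$pos, st0$clat$pos)
  expect_equal(out$time, 50 * 1e-4)
})

test_that("dissociation sweep matches the binomial closed form (1e5 trials)", {
  # 1e4 independent dimer bonds over 10 sweeps; each bond survives a sweep
  # with 1 - p, p = 1 - exp(-k dt), so the total break count is
  # Binomial(1e4, 1 - (1-p)^10)
  n_pairs <- 10000L
  dt <- 3e-5
  k_off <- -log(1 - 1e-3) / dt          # per-step p = 1e-3 exactly
  st <- dimer_field_state(n_pairs)
  cfg <- dissociation_config(attr(st, "edge_um"), k_off, dt)
  set.seed(12345)
  out <- sim_step(st, cfg, n_steps = 10)
  ev <- attr(out, "events")
  x <- sum(ev$type == 1)
  p_total <- 1 - (1 - 1e-3)^10
  expected <- n_pairs * p_total
  se <- sqrt(n_pairs * p_total * (1 - p_total))
  expect_lt(abs(x - expected), 3 * se)
  # and a binomial test does not reject at alpha = 0.01
  expect_gt(binom.test(x, n_pairs, p_total)$p.value, 0.01)
})

test_that("bond waiting times are exponential with rate k_off (KS, 1e4 events)", {
  n_pairs <- 10500L
  dt <- 3e-5
  k_off <- -log(1 - 3e-3) / dt
  st <- dimer_field_state(n_pairs)
  cfg <- dissociation_config(attr(st, "edge_um"), k_off, dt)
  n_steps <- 2000L
  set.seed(42)
  out <- sim_step(st, cfg, n_steps = n_steps)
  ev <- attr(out, "events")
  expect_gte(nrow(ev), 1e4)
  # event timestamps mark the start of the breaking step; the in-step break
  # instant is uniform, and the step-boundary survival is exactly
  # exp(-k_off t).  Compare against the right-truncated exponential.
  t_max <- n_steps * dt
  times <- ev$time_s + runif(nrow(ev), 0, dt)
  trunc_cdf <- function(q) pexp(q, k_off) / pexp(t_max, k_off)
  ks <- suppressWarnings(ks.test(times, trunc_cdf))
  expect_gt(ks$p.value, 0.01)
})

test_that("monomer and bonded-dimer MSD follow 2 n D dt", {
  # cytosolic monomers: 3D, per-axis squared increment = 2 D dt_frame
  cfg <- tiny_config()
  cfg$box$edge_length_um <- 5
  cfg$copy_numbers$n_clathrin <- 100L
  cfg$copy_numbers$n_ap2 <- 0L
  cfg$kinetics$k_clat_clat_on_uM_s <- 0
  cfg$kinetics$k_clat_ap2_on_uM_s <- 0
  cfg$kinetics$dt_s <- 3e-5
  st <- random_initial_state(cfg, seed = 8)
  st$ap2$pos <- matrix(numeric(0), 0, 2)
  st$ap2$bond <- integer(0)
  frame_dt <- 3e-4
  traj <- sim_run(st, cfg, duration = 0.075, frame_interval = frame_dt, seed = 21)
  P <- lapply(traj$frames, function(f) f$clat$pos)
  inc <- do.call(rbind, lapply(seq_len(length(P) - 1),
                               function(i) P[[i + 1]] - P[[i]]))
  expected <- 2 * cfg$kinetics$d_clat_trans_um2_s * 1e6 * frame_dt
  for (ax in 1:3) {
    msd <- mean(inc[, ax]^2)
    se <- sd(inc[, ax]^2) / sqrt(nrow(inc))
    expect_lt(abs(msd - expected), 3 * se + 0.02 * expected)
  }

  # membrane-anchored dimer: 2D with the cluster-combined coefficient
  cfg2 <- default_config()
  cfg2$box$edge_length_um <- 4
  cfg2$kinetics$k_clat_clat_on_uM_s <- 0
  cfg2$kinetics$k_clat_ap2_on_uM_s <- 0
  cfg2$kinetics$k_clat_clat_off_s <- 0
  cfg2$kinetics$k_clat_ap2_off_s <- 0
  cfg2$kinetics$dt_s <- 3e-5
  set.seed(9)
  st2 <- make_bond_graph(rep(2, 40), cfg2)
  traj2 <- sim_run(st2, cfg2, duration = 0.075, frame_interval = frame_dt, seed = 22)
  # centroid of each dimer's two clathrins per frame
  cent <- lapply(traj2$frames, function(f) {
    odd <- seq(1, nrow(f$clat$pos), by = 2)
    (f$clat$pos[odd, 1:2] + f$clat$pos[odd + 1, 1:2]) / 2
  })
  inc2 <- do.call(rbind, lapply(seq_len(length(cent) - 1),
                                function(i) cent[[i + 1]] - cent[[i]]))
  D_pred <- cluster_diffusion(c(rep(cfg2$kinetics$d_clat_trans_um2_s, 2),
                                cfg2$kinetics$d_ap2_trans_um2_s)) * 1e6
  expected2 <- 2 * D_pred * frame_dt
  for (ax in 1:2) {
    msd <- mean(inc2[, ax]^2)
    se <- sd(inc2[, ax]^2) / sqrt(nrow(inc2))
    expect_lt(abs(msd - expected2), 3 * se + 0.02 * expected2)
  }
  # membrane species never leave the anchoring plane
  expect_true(all(vapply(traj2$frames, function(f)
    max(abs(f$clat$pos[, 3] - cfg2$site_geometry$ap2_arm_length_nm)), 1) < 1e-9))
})

test_that("a reactive run preserves every model invariant at every frame", {
  cfg <- scaled_down_config()
  cfg$kinetics$k_clat_clat_off_s <- 100
  cfg$kinetics$d_ap2_trans_um2_s <- 0.05
  cfg$kinetics$k_clat_clat_on_uM_s <- 1.83 * 8
  st <- random_initial_state(cfg, seed = 31)
  traj <- suppressWarnings(
    sim_run(st, cfg, duration = 1.2, frame_interval = 0.1, seed = 31))
  geom <- do.call(site_geometry, cfg$site_geometry)
  L <- cfg$box$edge_length_um * 1e3
  n_ev <- sum(vapply(traj$frames, function(f) sum(f$clat$leg_bond > 0), 0L))
  expect_gt(n_ev, 0)    # something actually assembled
  for (f in traj$frames) {
    n <- nrow(f$clat$pos)
    # molecule conservation
    expect_identical(n, nrow(st$clat$pos))
    expect_identical(nrow(f$ap2$pos), nrow(st$ap2$pos))
    # containment and unit quaternions
    expect_true(all(f$clat$pos >= -1e-9 & f$clat$pos <= L + 1e-9))
    expect_equal(rowSums(f$clat$quat^2), rep(1, n), tolerance = 1e-9)
    # bond symmetry + exact 5 nm bond geometry
    bonded <- which(f$clat$leg_bond > 0, arr.ind = TRUE)
    for (r in seq_len(nrow(bonded))) {
      i <- unname(bonded[r, 1]); k <- unname(bonded[r, 2])
      j <- f$clat$leg_bond[i, k]; kj <- f$clat$leg_bond_site[i, k]
      expect_identical(f$clat$leg_bond[j, kj], i)
      si <- clathrin_sites(list(center = f$clat$pos[i, ], quat = f$clat$quat[i, ]), geom)
      sj <- clathrin_sites(list(center = f$clat$pos[j, ], quat = f$clat$quat[j, ]), geom)
      expect_equal(sqrt(sum((si[k, ] - sj[kj, ])^2)), geom$bond_length_nm,
                   tolerance = 1e-6)
    }
    # overlap freedom (bonded pairs exempt)
    pairs <- bonded
    bp <- if (nrow(pairs)) cbind(pairs[, 1], f$clat$leg_bond[pairs]) else NULL
    expect_false(detect_overlap(f$clat$pos, bp, geom))
    # membrane anchoring height and AP-2 bond symmetry
    mem <- f$clat$comp == 1
    if (any(mem))
      expect_equal(f$clat$pos[mem, 3], rep(geom$ap2_arm_length_nm, sum(mem)),
                   tolerance = 1e-9)
    b <- which(f$clat$ap2_bond > 0)
    expect_identical(f$ap2$bond[f$clat$ap2_bond[b]], b)
  }
})
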