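# Initial conditions, schedules and the sweep/EGF drivers (small cases;
# the directional trend suite lives in test-acceptance.R).

test_that("random_initial_state places molecules uniformly without overlap", {
  cfg <- tiny_config()
  cfg$copy_numbers$n_clathrin <- 0L
  cfg$copy_numbers$n_ap2 <- 0L
  empty <- random_initial_state(cfg, seed = 1)
  expect_identical(nrow(empty$clat$pos), 0L)

  cfg2 <- tiny_config()
  a <- random_initial_state(cfg2, seed = 4)
  b <- random_initial_state(cfg2, seed = 4)
  expect_identical(a, b)
  expect_true(all(a$clat$comp == 0L))
  expect_true(all(a$clat$leg_bond == 0L))
  geom <- do.call(site_geometry, cfg2$site_geometry)
  expect_false(detect_overlap(a$clat$pos, geom = geom))

  # z of dilute clathrins is uniform over [0, L] (KS at alpha = 0.01)
  cfg3 <- default_config()
  cfg3$box$edge_length_um <- 2
  cfg3$copy_numbers$n_clathrin <- 500L
  cfg3$copy_numbers$n_ap2 <- 0L
  z <- unlist(lapply(1:20, function(s)
    random_initial_state(cfg3, seed = 100 + s)$clat$pos[, 3]))
  expect_gte(length(z), 1e4)
  ks <- ks.test(z, "punif", 0, 2000)
  expect_gt(ks$p.value, 0.01)
})

test_that("single_cluster_initial_state builds a bonded anchored patch", {
  cfg <- scaled_down_config()
  one <- single_cluster_initial_state(cfg, 1, seed = 1)
  expect_identical(sum(one$clat$comp == 1), 1L)
  expect_identical(one$clat$ap2_bond[1], 1L)

  st <- single_cluster_initial_state(cfg, 7, seed = 2)
  geom <- do.call(site_geometry, cfg$site_geometry)
  cf <- identify_clusters(st, min_cluster_size = 1, geom = geom)
  expect_identical(cf$n_clusters, 1L)
  expect_identical(max(cf$cluster_sizes), 7L)
  bonded <- which(st$clat$leg_bond > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(bonded))) {
    i <- unname(bonded[r, 1]); k <- unname(bonded[r, 2])
    j <- st$clat$leg_bond[i, k]; kj <- st$clat$leg_bond_site[i, k]
    si <- clathrin_sites(list(center = st$clat$pos[i, ], quat = st$clat$quat[i, ]), geom)
    sj <- clathrin_sites(list(center = st$clat$pos[j, ], quat = st$clat$quat[j, ]), geom)
    expect_equal(sqrt(sum((si[k, ] - sj[kj, ])^2)), geom$bond_length_nm,
                 tolerance = 1e-9)
  }
  expect_false(detect_overlap(st$clat$pos,
                              cbind(bonded[, 1], st$clat$leg_bond[bonded]),
                              geom))
  expect_error(single_cluster_initial_state(cfg, 1000), "copy number")
})

test_that("sweep_spec validates its invariants", {
  expect_error(sweep_spec("k_clat_clat_fold", c(1, -2)), "> 0")
  expect_error(sweep_spec("ap2_number", c(10, 20), replicates = 2,
                          seeds = 1:3), "seeds")
  sp <- sweep_spec("ap2_number", c(10, 20), replicates = 2)
  expect_identical(sp$seeds, 1:4)
})

test_that("run_sweep returns one row per run and is seed-reproducible", {
  cfg <- tiny_config()
  cfg$kinetics$k_clat_clat_off_s <- 100
  sp <- sweep_spec("ap2_number", 10, replicates = 1, base_config = cfg,
                   duration = 0.3, frame_interval = 0.03, seeds = 7)
  out <- run_sweep(sp)
  expect_identical(nrow(out$runs), 1L)
  # duplicated value with identical seeds -> identical metric rows
  sp2 <- sweep_spec("ap2_number", 10, replicates = 2, base_config = cfg,
                    duration = 0.3, frame_interval = 0.03, seeds = c(7, 7))
  out2 <- run_sweep(sp2)
  expect_equal(out2$runs[1, -3], out2$runs[2, -3], ignore_attr = TRUE)
  expect_equal(out$runs$modal_cluster_number[1],
               out2$runs$modal_cluster_number[1])
})

test_that("apply_schedule follows the stimulus combinations and reversal", {
  s_step <- egf_schedule(combination = "ap2_only", ap2_ramp = "step",
                         t_switch = 100, t_end = 200)
  at10 <- apply_schedule(s_step, 10)
  expect_identical(at10$ap2_target, 200L)
  expect_equal(at10$k_fold, 1)
  expect_equal(at10$d_fold, 1)

  s_all <- egf_schedule(combination = "ap2_k_d", t_switch = 100, t_end = 200)
  at0 <- apply_schedule(s_all, 1e-9)
  expect_equal(at0$k_fold, 50)
  expect_equal(at0$d_fold, 1 / 50)
  # linear ramp midpoint
  mid <- apply_schedule(s_all, 50)
  expect_identical(mid$ap2_target, 150L)
  # reversal: everything back to baseline
  for (comb in c("ap2_only", "ap2_plus_k", "ap2_plus_d", "ap2_k_d")) {
    s <- egf_schedule(combination = comb, t_switch = 100, t_end = 200)
    after <- apply_schedule(s, 150)
    expect_identical(after$ap2_target, 100L)
    expect_equal(after$k_fold, 1)
    expect_equal(after$d_fold, 1)
  }
  expect_error(egf_schedule(t_switch = 10, t_end = 5), "t_switch")
})

test_that("AP-2 count adjustment inserts, removes free first, then force-unbinds", {
  cfg <- scaled_down_config()
  st <- single_cluster_initial_state(cfg, 7, seed = 3)
  m0 <- nrow(st$ap2$pos)
  up <- fclsim:::adjust_ap2_count(st, m0 + 5L, 500)
  expect_identical(nrow(up$state$ap2$pos), m0 + 5L)
  expect_identical(up$forced, 0L)
  # removing more than the free pool forces unbinding
  set.seed(1)
  n_free <- sum(st$ap2$bond == 0)
  down <- fclsim:::adjust_ap2_count(st, m0 - n_free - 2L, 500)
  expect_identical(nrow(down$state$ap2$pos), m0 - n_free - 2L)
  expect_identical(down$forced, 2L)
  # bond tables stay mutually consistent
  s2 <- down$state
  b <- which(s2$clat$ap2_bond > 0)
  expect_identical(s2$ap2$bond[s2$clat$ap2_bond[b]], b)
})

test_that("egf_experiment normalizes to t = 0 and is flat for frozen kinetics", {
  cfg <- tiny_config()
  cfg$copy_numbers$n_clathrin <- 12L
  cfg$copy_numbers$n_ap2 <- 10L
  for (f in c("k_clat_clat_on_uM_s", "k_clat_ap2_on_uM_s",
              "k_clat_clat_off_s", "k_clat_ap2_off_s"))
    cfg$kinetics[[f]] <- 0
  sched <- egf_schedule(ap2_start = 10, ap2_peak = 10, t_switch = 2, t_end = 4,
                        combination = "ap2_only")
  out <- egf_experiment(cfg, sched, n_cluster_init = 7, replicates = 1,
                        seeds = 1, segment = 1)
  expect_equal(out$curves$fold_number, rep(1, nrow(out$curves)))
  expect_equal(out$curves$fold_number[out$curves$time_s == 0], 1)
  expect_identical(out$forced_unbinds, 0L)
})

test_that("validate_well_mixed honors the trivial limits", {
  off <- validate_well_mixed(k_on = 0, k_off = 5, nA = 20, nB = 20,
                             duration = 0.01, dt = 1e-5, seed = 1)
  expect_identical(off$bound_fraction, 0)
  expect_equal(off$prediction, 0)
})
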