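# Rigid-body geometry, bound-pair placement, overlap and boundary rules.

test_that("site geometry is rigid: inter-site distances are pose-invariant", {
  set.seed(11)
  geom <- site_geometry()
  ref <- clathrin_sites(clathrin(c(0, 0, 0)), geom)
  ref_d <- dist(rbind(ref, c(0, 0, 0)))
  for (i in 1:50) {
    mol <- clathrin(runif(3, -500, 500), random_quaternion(1)[1, ])
    s <- clathrin_sites(mol, geom)
    expect_equal(as.numeric(dist(rbind(s, mol$center))), as.numeric(ref_d),
                 tolerance = 1e-12)
  }
  # legs are coplanar with the center and pairwise at 120 degrees
  v <- sweep(ref[1:3, ], 2, c(0, 0, 0))
  ang <- acos(sum(v[1, ] * v[2, ]) / (geom$leg_length_nm^2))
  expect_equal(ang, 2 * pi / 3, tolerance = 1e-12)
})

test_that("place_bound_pair produces exact head-to-head bound geometry", {
  geom <- site_geometry()
  h <- geom$ap2_arm_length_nm
  # membrane clathrin A, random cytosolic B docking onto leg 1
  set.seed(7)
  for (rep in 1:20) {
    A <- clathrin(c(500, 500, h), quat_about_z(runif(1, 0, 2 * pi)),
                  compartment = "membrane")
    B <- clathrin(runif(3, 0, 900), random_quaternion(1)[1, ])
    sa <- sample(1:3, 1); sb <- sample(1:3, 1)
    res <- place_bound_pair(A, sa, B, sb, geom)
    sA <- clathrin_sites(res$clatA, geom)
    sB <- clathrin_sites(res$clatB, geom)
    # bound sites 5 nm apart
    expect_equal(sqrt(sum((sA[sa, ] - sB[sb, ])^2)), geom$bond_length_nm,
                 tolerance = 1e-9)
    # head-to-head: sites collinear with the two centers
    axis <- res$clatB$center - res$clatA$center
    gap <- sB[sb, ] - sA[sa, ]
    expect_equal(abs(sum(axis * gap)) / sqrt(sum(axis^2)) / sqrt(sum(gap^2)),
                 1, tolerance = 1e-9)
    # coplanar: both centers and all six leg sites share the membrane plane
    zs <- c(res$clatA$center[3], res$clatB$center[3], sA[1:3, 3], sB[1:3, 3])
    expect_true(max(abs(zs - h)) < 1e-9)
  }
})

test_that("place_bound_pair is the identity for an already-placed partner", {
  geom <- site_geometry()
  A <- clathrin(c(100, 100, 100), random_quaternion(1)[1, ])
  B0 <- clathrin(c(300, 50, 80), random_quaternion(1)[1, ])
  placed <- place_bound_pair(A, 1, B0, 2, geom)$clatB
  placed$bonds[] <- 0L
  again <- place_bound_pair(A, 1, placed, 2, geom)$clatB
  expect_equal(again$center, placed$center, tolerance = 1e-9)
  expect_equal(abs(sum(again$quat * placed$quat)), 1, tolerance = 1e-9)
})

test_that("place_bound_pair rejects occupied sites and off-plane membrane moves", {
  geom <- site_geometry()
  A <- clathrin(c(0, 0, 0), bonds = c(1L, 0L, 0L, 0L))
  B <- clathrin(c(100, 0, 0))
  expect_error(place_bound_pair(A, 1, B, 1, geom), "occupied")
  # a membrane-flagged B cannot be placed against a tilted cytosolic A
  tiltA <- clathrin(c(0, 0, 200), c(cos(0.4), sin(0.4), 0, 0))
  memB <- clathrin(c(100, 0, 7.5), compartment = "membrane")
  expect_error(place_bound_pair(tiltA, 1, memB, 1, geom), "membrane")
})

test_that("detect_overlap applies the 20 nm hard core with bonded exemption", {
  geom <- site_geometry()
  two <- function(d) rbind(c(0, 0, 0), c(d, 0, 0))
  expect_false(detect_overlap(two(30), geom = geom))
  expect_true(detect_overlap(two(15), geom = geom))
  expect_false(detect_overlap(two(15), bonded = cbind(1, 2), geom = geom))
  expect_false(detect_overlap(two(30)[1, , drop = FALSE], geom = geom))
})

test_that("apply_boundaries reflects, wraps and rejects pathological moves", {
  box_r <- box_geometry(1, "reflecting")
  box_p <- box_geometry(1, "periodic")
  expect_equal(apply_boundaries(c(0.5, 0.5, -0.01), box_r), c(0.5, 0.5, 0.01))
  expect_equal(apply_boundaries(c(0.3, 0.9, 0.2), box_r), c(0.3, 0.9, 0.2))
  expect_equal(apply_boundaries(c(1.02, 0.5, 0.5), box_p), c(0.02, 0.5, 0.5))
  expect_equal(apply_boundaries(c(1.02, 0.5, 0.5), box_r), c(0.98, 0.5, 0.5))
  expect_error(apply_boundaries(c(3.5, 0.5, 0.5), box_r), "exceeds")
  # idempotent on in-box positions
  p <- c(0.1, 0.99, 0.5)
  expect_identical(apply_boundaries(apply_boundaries(p, box_p), box_p),
                   apply_boundaries(p, box_p))
})
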