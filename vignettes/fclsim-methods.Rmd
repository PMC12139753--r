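---
title: "Modeling flat clathrin lattice dynamics with fclsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling flat clathrin lattice dynamics with fclsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

Flat clathrin lattices (FCLs) are long-lived planar clathrin assemblies on
the plasma membrane that act as signaling platforms, in contrast to the
transient Omega-shaped pits of endocytosis. `fclsim` simulates their
assembly and disassembly with a coarse-grained, particle-based
reaction-diffusion model on a cubic membrane patch:

* **Geometry.** The domain is a cube (default edge 1 um); its z = 0 face is
  the membrane, the volume above is cytosol. Boundaries are reflecting
  (lateral periodic optional).
* **Clathrin** is a rigid triskelion: a hub with three leg binding sites at
  120 degrees in the molecule plane and one adaptor (AP-2) site on the
  axis normal to that plane. Clathrin diffuses in the cytosol (3D) or,
  when anchored, in the membrane plane (2D), with translational and
  rotational Brownian motion.
* **AP-2** is a point-like adaptor confined to the membrane plane.
* **Reactions.** A clathrin adaptor site binds a free AP-2; a clathrin leg
  binds, head-to-head, a leg of an AP-2-bound clathrin. All bonds are
  reversible. Bound leg sites sit exactly 5 nm apart with both molecule
  planes coplanar, so membrane lattices are flat honeycombs with hub
  spacing `2 * leg_length + 5` nm. A hard core of radius 10 nm acts
  between non-bonded hubs.
* **Stepping.** Each timestep tests dissociations first (probability
  `1 - exp(-k_off * dt)` per bond), then associations, then diffuses every
  molecule or rigid complex that did not react. A molecule undergoes at
  most one reaction per step. Assembled complexes move as one unit with
  `D = (sum_i D_i^(-1/n))^(-n)` (`n = 1` translation, `n = 3` rotation);
  displacements are `sqrt(2 D dt)` Gaussians, and moves that would overlap
  hard cores are resampled (bounded retries).

### Association scheme

Associations use a Doi/contact acceptance: a reactive site pair within
`sigma_react` (default 10 nm) reacts with probability
`1 - exp(-k_micro dt)`, where `k_micro = k_on / ((4/3) pi sigma^3)` in 3D.
When both partners are membrane-bound the volumetric on-rate is first
divided by `rate_2d_lengthscale` (default `2 sigma`). In the
reaction-limited regime this reproduces the macroscopic mass-action flux
`k_on [A][B]`; the contract is validated against the closed-form
mass-action equilibrium by `validate_well_mixed()` (and by the acceptance
suite, three dissociation constants spanning a 100-fold range, agreement
within three Monte-Carlo standard errors). A full propagator-reweighting
backend would refine the diffusion-influenced correction but is not needed
for the quantities this package reports.

### Who may bind whom

The recruitment reaction is written between an *AP-2-bound* clathrin and
another clathrin. `fclsim` therefore requires, by default, that one
partner of every new leg-leg bond is directly anchored to an AP-2
(`cc_requires_ap2_bound = TRUE`); closing a ring inside one lattice is
exempt, since there the bond is gated by geometry, not recruitment, and
free-solution dimerization is off (`allow_solution_dimerization = FALSE`).
This rule caps the membrane population at what the adaptors can hold --
the feature that makes adaptor number the master regulator of lattice
mass. Relaxing it to "any membrane-associated partner" lets lattices grow
without bound through non-anchored members.

## Parameters

| parameter | default | origin |
|---|---|---|
| box edge | 1 um | stated domain size |
| `dt_s` | 3e-6 s | stated timestep |
| bound-site separation | 5 nm | stated |
| excluded-volume radius | 10 nm | stated |
| `k_clat_clat_on_uM_s` | 1.83 | stated baseline on-rate |
| `d_clat_trans_um2_s` | 13 | stated clathrin diffusivity |
| `leg_length_nm` | 12.5 | repo choice: hub spacing 30 nm, a realistic flat-lattice spacing comfortably above the 20 nm hard-core diameter |
| `ap2_arm_length_nm` | 7.5 | repo choice (anchoring height) |
| `k_clat_clat_off_s` | 100 | repo calibration, see below |
| `k_clat_ap2_on_uM_s` / `off` | 2.0 / 0.1 | repo choice: near-saturating adaptor occupancy at cytosolic ~0.7 uM clathrin |
| `d_ap2_trans_um2_s` | 0.05 | repo choice: typical membrane-protein mobility |
| `d_clat_rot_s` | 3e4 | Stokes-Einstein at the radius implied by D = 13 um^2/s |
| `n_clathrin` / `n_ap2` | 400 / 150 | repo choice / stated baseline adaptor count |

The unpublished values (off-rates, adaptor kinetics, copy number, adaptor
mobility) were fixed once against the model's stated baseline phenotype: at
AP-2 = 150 and an elevated clathrin-clathrin on-rate, a handful of mutually
avoiding, highly dynamic clusters of ~0.02-0.1 um^2 whose membrane
population is adaptor-limited. A weak single leg-leg bond
(K_D ~ 55 uM at the baseline on-rate) is essential: individual bonds churn
in ~10 ms, lattice interiors persist through avidity (up to three legs plus
instant in-lattice rebinding), and clusters exchange members continuously --
which is exactly what makes the cluster-number time series "dynamic".

## Cluster statistics

`identify_clusters()` labels connected components of the leg-bond graph
restricted to membrane-associated clathrins; a component is a *cluster*
only if it has at least `min_cluster_size` members (default 5 -- the
threshold suppresses transient dimers/trimers; the source data never
states one) and at least one AP-2 anchor. Cluster area is the convex hull
of the members' projected hubs and leg sites, dilated by `hull_pad_nm`
(default 5 nm, half the hard-core radius); an alpha-shape would follow
concave lattices more closely but the hull is reproducible and
orientation-free. Degenerate hulls fall back to the dilated segment/disc
formulas.

`summarize_trajectory()` implements the trajectory metrics: the
equilibration time `t_c` (first time the membrane-bound clathrin count
reaches 90% of its end-of-run value), the *most possible pattern* (modal
cluster number over post-`t_c` frames, ties to the smaller number), the
mean over modal-pattern frames of the mean cluster size (total cluster
area / cluster count), and the mean dwelling time (run lengths of the
cluster-number series; segments touching the trace boundary are censored
and excluded from means). Quartile summaries (`area_stats()`) use type-7
linear interpolation with Tukey 1.5 IQR fences; group comparisons
(`compare_groups()`) are unpaired Welch t-tests by default.

## The synthetic-data generators

`make_cluster_trace()` emulates only the *statistical* structure the
metrics consume -- a Markov cluster-number chain with lognormal per-cluster
areas -- so the mode, the geometric dwell law
(`frame_interval / (1 - p_self)`) and the expected mean area
(`exp(mu + sigma^2/2)`) are known exactly. `make_bond_graph()` builds
geometrically exact honeycomb components; `make_point_pattern()` embeds a
brute-force neighbor count. A green recovery test therefore establishes
that the analysis code measures what it claims on data with known truth;
it does not establish anything about spatial assembly kinetics, which is
the simulator's job.

## The scaled-down desk world

Faithful replication of a production run (30 simulated minutes at
dt = 3 us) costs ~6e8 steps per replicate and is not desk-scale. The test
preset (`scaled_down_config()`) keeps the full 1 um membrane patch --
a half-size patch cannot hold more than one cluster, which silences every
cluster-number observable -- and compresses *time* instead: dt = 4.5e-5 s
and windows of 5-16 s. Two consequences are documented rather than hidden:

* At large on-rate folds the per-step acceptance saturates
  (`p -> 1`), so the top of a fold grid is effectively diffusion-limited;
  a warning is emitted whenever `p > 0.1`.
* Every run is kinetically *young*: the slow late-stage coarsening that, in
  a 30-minute run, concentrates mass into few large clusters at the
  baseline on-rate has no desk-scale counterpart. The directions that
  survive the compression (adaptor-number rise-and-fall of the cluster
  count, monotone size growth with adaptor number, cluster-count growth
  with binding rate, all diffusion-coefficient directions, the
  growth-factor fold-change shape) are asserted green in
  `test-acceptance.R`; the two that require the coarsened low-rate
  reference state (size and dwell decreasing with binding rate) fail at
  desk scale and are deliberately left red with this analysis.

## Protocols

`run_sweep()` drives replicate simulations over adaptor number, on-rate
fold, or diffusivity fold, and reports per-run metrics, group mean +/- SD
and consecutive-value Welch tests. `egf_experiment()` mimics growth-factor
stimulation from a single-cluster initial state: AP-2 ramps linearly
(ramp shape is not specified by the source; a step option exists), the
on-rate is multiplied by `k_fold` (default 50) and the diffusivity by
`d_fold` (default 1/50) from t = 0, and everything reverts at `t_switch`;
insertions are uniform on the membrane, removals take free adaptors first
and force-unbind only when necessary (counted and reported). Outputs are
cluster-number and maximum-cluster-area fold changes normalized to t = 0.

## Numerical notes

* Orientations are unit quaternions, renormalized at every update;
  membrane molecules are snapped to exact in-plane poses (center height =
  adaptor arm length, pure z-rotations) after each rigid placement.
* Rigid placements are exact: bound sites land 5 nm apart head-to-head to
  machine precision, which the invariant suite checks at 1e-6 nm on every
  recorded frame.
* Overlapping diffusion moves are resampled up to `max_move_retries`
  (default 100), then skipped and counted (`skipped_moves`).
* Reflecting boundaries use mirror folding for point-like moves and
  displacement reversal for rigid complexes (a mirror would flip
  chirality).
* All randomness flows from R's RNG seed; the engine draws from an
  internal xoshiro256++ stream seeded from it, so `set.seed()` makes whole
  trajectories bit-reproducible.
* A uniform cell grid (cell size >= every interaction cutoff, at most
  16^3 cells) backs neighbor searches, overlap tests and placement checks.

## Limitations

Membrane mechanics (the flat-to-curved transition), lipid composition,
explicit AP-2/membrane binding kinetics, receptor signaling biochemistry
and micrograph segmentation are out of scope. The desk-scale tests
establish directional, not quantitative, agreement; quantitative
modal-pattern values would require production-scale runs.
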