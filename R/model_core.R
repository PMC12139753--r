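# Rigid-body geometry of the triskelion model.
#
# Body frame: center at the origin, the three leg sites in the xy-plane at
# 0/120/240 degrees at distance leg_length, the AP-2 arm along -z at
# ap2_arm_length.  A membrane-bound molecule has its plane parallel to
# z = 0, arm pointing at the membrane, center at z = ap2_arm_length.

#' Construct a clathrin molecule record
#'
#' @param center Numeric length-3 position of the hub, nm.
#' @param quat Unit quaternion (w, x, y, z) giving the body orientation.
#' @param compartment `"cytosol"` or `"membrane"`.
#' @param bonds Integer length-4 vector of partner ids (0 = free): three leg
#'   sites then the AP-2 site.
#' @return A list of class `fcl_clathrin`.
#' @export
clathrin <- function(center, quat = c(1, 0, 0, 0),
                     compartment = c("cytosol", "membrane"),
                     bonds = integer(4)) {
  compartment <- match.arg(compartment)
  stopifnot(length(center) == 3, length(quat) == 4, length(bonds) == 4)
  quat <- quat / sqrt(sum(quat^2))
  structure(list(center = as.numeric(center), quat = as.numeric(quat),
                 compartment = compartment, bonds = as.integer(bonds)),
            class = "fcl_clathrin")
}

#' Site geometry parameters
#'
#' @param bond_length_nm Distance between two bound leg sites (head-to-head).
#' @param excluded_volume_radius_nm Hard-core radius of a clathrin hub;
#'   non-bonded centers may not approach closer than twice this value.
#' @param leg_length_nm Center-to-leg-site arm length.
#' @param ap2_arm_length_nm Center-to-adaptor-site arm length.
#' @return A list of class `fcl_site_geometry`.
#' @export
site_geometry <- function(bond_length_nm = 5, excluded_volume_radius_nm = 10,
                          leg_length_nm = 12.5, ap2_arm_length_nm = 7.5) {
  vals <- c(bond_length_nm, excluded_volume_radius_nm, leg_length_nm,
            ap2_arm_length_nm)
  if (any(vals <= 0)) stop("all site geometry lengths must be > 0")
  structure(list(bond_length_nm = bond_length_nm,
                 excluded_volume_radius_nm = excluded_volume_radius_nm,
                 leg_length_nm = leg_length_nm,
                 ap2_arm_length_nm = ap2_arm_length_nm),
            class = "fcl_site_geometry")
}

#' Box geometry
#'
#' The simulation domain is a cube; the z = 0 face is the membrane plane.
#' The vertical boundary is always reflecting; the lateral boundary is
#' reflecting by default with a periodic option.
#'
#' @param edge_length_um Cube edge, um.
#' @param lateral_boundary `"reflecting"` or `"periodic"`.
#' @return A list of class `fcl_box`.
#' @export
box_geometry <- function(edge_length_um = 1,
                         lateral_boundary = c("reflecting", "periodic")) {
  lateral_boundary <- match.arg(lateral_boundary)
  if (edge_length_um <= 0) stop("edge_length_um must be > 0")
  structure(list(edge_length_um = edge_length_um,
                 lateral_boundary = lateral_boundary),
            class = "fcl_box")
}

#' Binding-site positions of a clathrin molecule
#'
#' @param mol A [clathrin()] record (or any list with `center` and `quat`).
#' @param geom A [site_geometry()] record.
#' @return A 4 x 3 matrix: rows are the three leg sites then the AP-2 site,
#'   columns x/y/z in nm.
#' @export
clathrin_sites <- function(mol, geom = site_geometry()) {
  cpp_sites(mol$center, mol$quat, geom$leg_length_nm, geom$ap2_arm_length_nm)
}

#' Place two clathrins in bound geometry
#'
#' Applies the rigid transform to `clatB` (the unanchored partner) so that
#' leg `siteA` of `clatA` and leg `siteB` of `clatB` are head-to-head:
#' the two sites sit `bond_length_nm` apart on the line through the two
#' centers, and the two molecule planes are coplanar with consistent
#' normals. `clatA` is never moved.
#'
#' @param clatA,clatB [clathrin()] records.
#' @param siteA,siteB Leg site indices in 1..3.
#' @param geom A [site_geometry()] record.
#' @return A list with the unchanged `clatA` and the transformed `clatB`,
#'   both with the new bond recorded.
#' @export
place_bound_pair <- function(clatA, siteA, clatB, siteB,
                             geom = site_geometry()) {
  if (!siteA %in% 1:3 || !siteB %in% 1:3)
    stop("siteA and siteB must be leg sites (1..3)")
  if (clatA$bonds[siteA] != 0 || clatB$bonds[siteB] != 0)
    stop("binding site already occupied")
  res <- cpp_place_pair(clatA$center, clatA$quat, as.integer(siteA),
                        clatB$center, clatB$quat, as.integer(siteB),
                        geom$leg_length_nm, geom$ap2_arm_length_nm,
                        geom$bond_length_nm)
  newB <- clatB
  newB$center <- res$center
  newB$quat <- res$quat
  if (identical(clatB$compartment, "membrane")) {
    nrm <- quat_rotate(newB$quat, c(0, 0, 1))
    if (abs(nrm[3]) < 1 - 1e-9)
      stop("no transform keeps the membrane-anchored partner in its plane")
  }
  clatA$bonds[siteA] <- 1L
  newB$bonds[siteB] <- 1L
  list(clatA = clatA, clatB = newB)
}

#' Excluded-volume overlap test
#'
#' TRUE iff any non-bonded pair of clathrin centers is closer than twice
#' the excluded-volume radius. Directly bonded partners are exempt (their
#' geometry is fixed by the bond, not by the hard core).
#'
#' @param centers n x 3 matrix of clathrin centers, nm.
#' @param bonded Optional 2-column matrix of bonded index pairs.
#' @param geom A [site_geometry()] record.
#' @return Logical scalar.
#' @export
detect_overlap <- function(centers, bonded = NULL, geom = site_geometry()) {
  centers <- rbind(centers)
  n <- nrow(centers)
  if (n < 2) return(FALSE)
  lim2 <- (2 * geom$excluded_volume_radius_nm)^2
  exempt <- matrix(FALSE, n, n)
  if (!is.null(bonded) && length(bonded)) {
    bonded <- rbind(bonded)
    exempt[bonded] <- TRUE
    exempt[bonded[, 2:1, drop = FALSE]] <- TRUE
  }
  d2 <- as.matrix(stats::dist(centers))^2
  diag(d2) <- Inf
  any(d2 < lim2 & !exempt)
}

#' Apply box boundary conditions to a position
#'
#' Reflects the z coordinate into `[0, L]`; reflects or wraps the lateral
#' coordinates according to the box's lateral boundary. Idempotent for
#' in-box positions. A displacement larger than the box edge signals a
#' pathological timestep/diffusion combination and is an error.
#'
#' @param pos Numeric length-3 position in um (same unit as the box edge).
#' @param box A [box_geometry()] record.
#' @return The folded position.
#' @export
apply_boundaries <- function(pos, box = box_geometry()) {
  L <- box$edge_length_um
  stopifnot(length(pos) == 3)
  if (any(pos < -L) || any(pos > 2 * L))
    stop("displacement exceeds the box edge; reduce dt or D")
  reflect <- function(x) {
    while (x < 0 || x > L) x <- if (x < 0) -x else 2 * L - x
    x
  }
  out <- pos
  out[3] <- reflect(pos[3])
  if (identical(box$lateral_boundary, "periodic")) {
    out[1:2] <- pos[1:2] - L * floor(pos[1:2] / L)
  } else {
    out[1] <- reflect(pos[1])
    out[2] <- reflect(pos[2])
  }
  out
}

# ---- quaternion helpers (R mirrors of the engine's conventions) ----------

#' Rotate a vector by a unit quaternion
#' @param q Quaternion (w, x, y, z).
#' @param v Numeric length-3 vector.
#' @return The rotated vector.
#' @export
quat_rotate <- function(q, v) {
  w <- q[1]; u <- q[2:4]
  v + 2 * w * cross3(u, v) + 2 * cross3(u, cross3(u, v))
}

#' Quaternion product
#' @param a,b Quaternions (w, x, y, z).
#' @return The product quaternion `a b`.
#' @export
quat_multiply <- function(a, b) {
  c(a[1] * b[1] - sum(a[2:4] * b[2:4]),
    a[1] * b[2:4] + b[1] * a[2:4] + cross3(a[2:4], b[2:4]))
}

#' Uniform random unit quaternion
#' @param n Number of quaternions.
#' @return An n x 4 matrix of unit quaternions.
#' @export
random_quaternion <- function(n = 1) {
  q <- matrix(stats::rnorm(4 * n), n, 4)
  q / sqrt(rowSums(q^2))
}

# quaternion for a rotation about z by angle (radians)
quat_about_z <- function(angle) c(cos(angle / 2), 0, 0, sin(angle / 2))

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
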