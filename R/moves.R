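# Monte Carlo move set.  All proposal kernels are symmetric (Gaussian or
# uniform draws, axis constructions independent of the drawn angle), so
# Metropolis acceptance needs no Hastings correction.  Every move is a
# rigid rotation of a subset of atoms, so no move ever changes a bond
# length.
#
# Draw protocol (kept in lockstep with the compiled MC loop, so an R-level
# step and the C++ loop are bit-identical under the same seed):
#   dihedral : u_pick, z_angle
#   concerted: u_pick, z_angle
#   rigid    : u_z, u_azimuth, u_angle

#' Single-dihedral pivot move
#'
#' Picks one rotatable dihedral uniformly and rotates its downstream atoms
#' about the pivot bond by an angle drawn from a centered Gaussian.
#'
#' @param sys a `molecular_system`.
#' @param dihedrals a [build_rotatable_dihedrals()] set.
#' @param xyz current coordinates.
#' @param width_deg Gaussian width (standard deviation) of the angle
#'   change, degrees.
#' @return A `move_proposal`: list with `xyz` (proposed coordinates),
#'   `kind`, `changed` (moved atom indices), and `meta` (chosen torsion /
#'   window and drawn angle in degrees; `meta$inverse_angle_deg` applied to
#'   the proposal reconstructs the input).
#' @export
dihedral_move <- function(sys, dihedrals, xyz, width_deg = 20) {
  nd <- length(dihedrals)
  if (nd == 0) stop("empty rotatable dihedral set")
  m <- min(floor(runif(1) * nd) + 1, nd)
  ang <- rnorm(1) * (width_deg * pi / 180)
  d <- dihedrals[[m]]
  new <- cpp_rotate_about_axis(xyz, d$downstream - 1L,
                               xyz[d$bond[1], ], xyz[d$bond[2], ], ang)
  structure(list(xyz = new, kind = "dihedral", changed = d$downstream,
                 meta = list(index = m, angle_deg = ang * 180 / pi,
                             bond = d$bond,
                             inverse_angle_deg = -ang * 180 / pi)),
            class = "move_proposal")
}

# window table for concerted moves: for each contiguous run of
# `window` residues, the anchors are the first residue's backbone N and the
# last residue's backbone C; everything in the window except the anchors
# rotates about the anchor-anchor axis.
concerted_windows <- function(sys, window = 4L) {
  res <- sort(unique(sys$atoms$resid))
  if (length(res) < window + 2)
    stop("chain too short for concerted moves (needs >= window + 2 residues)")
  a <- sys$atoms
  wins <- list()
  for (s in seq_len(length(res) - window + 1L)) {
    rr <- res[s:(s + window - 1L)]
    a1 <- which(a$name == "N" & a$resid == rr[1])[1]
    a2 <- which(a$name == "C" & a$resid == rr[window])[1]
    if (is.na(a1) || is.na(a2)) next
    moved <- setdiff(which(a$resid %in% rr), c(a1, a2))
    wins[[length(wins) + 1L]] <- list(a1 = a1, a2 = a2, moved = moved)
  }
  wins
}

#' Endpoint-constrained concerted (crankshaft) move
#'
#' Chooses a contiguous window of `window_residues` residues uniformly and
#' rotates all of its atoms rigidly about the axis through the window's
#' first backbone N and last backbone C by a Gaussian angle.  The two
#' anchor atoms and everything outside the window stay exactly fixed, so
#' the segment's endpoints do not change; several backbone dihedrals inside
#' the window change at once, and only the two junction bond angles are
#' strained (the angle term scores them).
#'
#' @inheritParams dihedral_move
#' @param window_residues window length in residues.
#' @return a `move_proposal` (see [dihedral_move()]).
#' @export
concerted_move <- function(sys, xyz, width_deg = 20, window_residues = 4L) {
  wins <- concerted_windows(sys, window_residues)
  nw <- length(wins)
  if (nw == 0) stop("no usable concerted windows")
  m <- min(floor(runif(1) * nw) + 1, nw)
  ang <- rnorm(1) * (width_deg * pi / 180)
  w <- wins[[m]]
  new <- cpp_rotate_about_axis(xyz, w$moved - 1L, xyz[w$a1, ], xyz[w$a2, ],
                               ang)
  structure(list(xyz = new, kind = "concerted", changed = w$moved,
                 meta = list(index = m, angle_deg = ang * 180 / pi,
                             anchors = c(w$a1, w$a2),
                             inverse_angle_deg = -ang * 180 / pi)),
            class = "move_proposal")
}

#' Whole-molecule rigid rotation
#'
#' Rotates all atoms about a uniformly distributed random axis through the
#' geometric center by an angle uniform on `[0, max_deg]`.  An isometry
#' that leaves the geometric center fixed; with a translation- and
#' rotation-invariant energy it is always accepted.
#'
#' @param xyz coordinates (`>= 2` atoms).
#' @param max_deg maximum rotation angle, degrees.
#' @return a `move_proposal` (see [dihedral_move()]).
#' @export
rigid_rotation_move <- function(xyz, max_deg = 5) {
  if (nrow(xyz) < 2) stop("rigid rotation needs at least 2 atoms")
  z <- 2 * runif(1) - 1
  az <- 2 * pi * runif(1)
  ang <- runif(1) * (max_deg * pi / 180)
  rho <- sqrt(max(0, 1 - z^2))
  cen <- cpp_geometric_center(xyz)
  p2 <- cen + c(rho * cos(az), rho * sin(az), z)
  new <- cpp_rotate_about_axis(xyz, seq_len(nrow(xyz)) - 1L, cen, p2, ang)
  structure(list(xyz = new, kind = "rigid", changed = seq_len(nrow(xyz)),
                 meta = list(axis_point = p2, center = cen,
                             angle_deg = ang * 180 / pi,
                             inverse_angle_deg = -ang * 180 / pi)),
            class = "move_proposal")
}

#' Draw a move kind
#'
#' Categorical draw over the three move kinds.  The defaults give the
#' dihedral and concerted moves equal probability, with a small rigid-
#' rotation share.
#'
#' @param move_weights nonnegative weights for
#'   `c(dihedral, concerted, rigid)`; must not all be zero.
#' @return one of `"dihedral"`, `"concerted"`, `"rigid"`.
#' @export
select_move <- function(move_weights = c(0.45, 0.45, 0.10)) {
  if (length(move_weights) != 3 || any(move_weights < 0) ||
      sum(move_weights) <= 0)
    stop("move weights must be 3 nonnegative values with positive sum")
  w <- move_weights / sum(move_weights)
  u <- runif(1)
  if (u < w[1]) "dihedral" else if (u < w[1] + w[2]) "concerted" else "rigid"
}

#' Reconstruct the pre-move coordinates from a proposal
#'
#' Applies the recorded inverse transform; round-tripping restores the
#' input coordinates to floating-point accuracy, which is the operational
#' statement of proposal symmetry.
#'
#' @param proposal a `move_proposal`.
#' @param sys the system (needed to rebuild window/dihedral geometry).
#' @param dihedrals the rotatable set used to generate the proposal.
#' @param window_residues window length used for concerted proposals.
#' @return coordinate matrix.
#' @export
invert_move <- function(proposal, sys = NULL, dihedrals = NULL,
                        window_residues = 4L) {
  p <- proposal
  ang <- p$meta$inverse_angle_deg * pi / 180
  if (p$kind == "dihedral") {
    d <- dihedrals[[p$meta$index]]
    cpp_rotate_about_axis(p$xyz, d$downstream - 1L,
                          p$xyz[d$bond[1], ], p$xyz[d$bond[2], ], ang)
  } else if (p$kind == "concerted") {
    a <- p$meta$anchors
    cpp_rotate_about_axis(p$xyz, p$changed - 1L, p$xyz[a[1], ],
                          p$xyz[a[2], ], ang)
  } else {
    cpp_rotate_about_axis(p$xyz, p$changed - 1L, p$meta$center,
                          p$meta$axis_point, ang)
  }
}
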