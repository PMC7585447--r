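# Energy evaluation.  The functional forms are the AMBER conventions:
#   E_bond    = sum k_b (r - r0)^2
#   E_angle   = sum k_th (theta - th0)^2
#   E_torsion = sum k (1 + cos(n phi - phase))
#   E_LJ/E_Coulomb over all non-excluded pairs, 1-4 pairs scaled by 0.5
#     (LJ) and 1/1.2 (Coulomb), no cutoffs, with every distance offset by
#     the delta regularization.
# Polar solvation is a generalized Born term (OBC-II pairwise-descreening
# radii, Still f_GB, self terms included); nonpolar solvation is
# gamma * SASA with Shrake-Rupley areas on LJ-derived radii.

#' Pack a system for the compiled energy kernels
#'
#' Precomputes the non-excluded pair list with folded-in 1-4 scalings and
#' Lorentz-Berthelot combined Lennard-Jones coefficients, the
#' generalized-Born descreening parameters and the sphere quadrature
#' points.  The pack depends only on topology and parameters, never on
#' coordinates, so it is built once per system and reused for every
#' energy evaluation.
#'
#' @param sys a `molecular_system`.
#' @param params a [solvent_params()].
#' @param terms character subset of
#'   `c("bonded", "nonbonded", "gb", "sasa")`.
#' @return an opaque list consumed by the compiled kernels.
#' @keywords internal
pack_energy <- function(sys, params = solvent_params(),
                        terms = c("bonded", "nonbonded", "gb", "sasa")) {
  terms <- match.arg(terms, several.ok = TRUE)
  n <- nrow(sys$atoms)

  # non-excluded pair list
  key <- function(i, j) (pmin(i, j) - 1) * n + pmax(i, j)
  all_i <- rep(seq_len(n - 1), times = (n - 1):1)
  all_j <- sequence((n - 1):1) + all_i
  drop <- key(all_i, all_j) %in% key(sys$exclusions[, 1], sys$exclusions[, 2])
  nb_i <- all_i[!drop]; nb_j <- all_j[!drop]
  is14 <- key(nb_i, nb_j) %in% key(sys$pairs14[, 1], sys$pairs14[, 2])
  sig <- (sys$lj_sigma[nb_i] + sys$lj_sigma[nb_j]) / 2
  eps <- sqrt(sys$lj_eps[nb_i] * sys$lj_eps[nb_j])
  ljs <- ifelse(is14, params$scale_lj14, 1)
  qs <- ifelse(is14, params$scale_coul14, 1)
  s6 <- sig^6
  nb_a <- 4 * eps * s6 * s6 * ljs
  nb_b <- 4 * eps * s6 * ljs
  nb_qq <- params$k_e * sys$charge[nb_i] * sys$charge[nb_j] * qs / params$eps_p

  use_gb <- "gb" %in% terms
  rho <- sys$gb_radius - params$gb_offset
  if (use_gb && any(sys$charge != 0) && any(sys$gb_radius <= 0))
    stop("nonpositive intrinsic GB radius")
  scr <- params$gb_screen[sys$atoms$element]
  scr[is.na(scr)] <- params$gb_screen_default
  gb_pref <- -0.5 * params$k_e * (1 / params$eps_p - 1 / params$eps_w)

  list(
    use_bonded = "bonded" %in% terms, use_nb = "nonbonded" %in% terms,
    use_gb = use_gb, use_sasa = "sasa" %in% terms,
    delta = params$delta,
    b_i = as.integer(sys$bonds$ai - 1L), b_j = as.integer(sys$bonds$aj - 1L),
    b_kb = sys$bonds$kb, b_r0 = sys$bonds$r0,
    a_i = as.integer(sys$angles$ai - 1L),
    a_j = as.integer(sys$angles$aj - 1L),
    a_k = as.integer(sys$angles$ak - 1L),
    a_kth = sys$angles$kth, a_th0 = sys$angles$th0,
    d_i = as.integer(sys$dihedrals$ai - 1L),
    d_j = as.integer(sys$dihedrals$aj - 1L),
    d_k = as.integer(sys$dihedrals$ak - 1L),
    d_l = as.integer(sys$dihedrals$al - 1L),
    d_kphi = sys$dihedrals$kphi, d_per = as.numeric(sys$dihedrals$per),
    d_phase = sys$dihedrals$phase,
    d_improper = as.integer(sys$dihedrals$improper),
    nb_i = as.integer(nb_i - 1L), nb_j = as.integer(nb_j - 1L),
    nb_qq = nb_qq, nb_a = nb_a, nb_b = nb_b,
    charge = sys$charge, gb_rho = rho, gb_sj = unname(scr * rho),
    gb_rint = sys$gb_radius,
    gb_alpha = params$gb_alpha, gb_beta = params$gb_beta,
    gb_gamma = params$gb_gamma, gb_pref = gb_pref,
    sasa_rad = sasa_radii(sys), probe = params$probe,
    gamma_kcal = params$gamma / 1000,
    sphere_pts = sphere_points(params$sasa_points)
  )
}

# LJ-derived SASA radii: position of the LJ minimum, r = 2^(1/6) sigma / 2
sasa_radii <- function(sys) {
  r <- 2^(1 / 6) * sys$lj_sigma / 2
  r[sys$lj_sigma <= 0] <- 0
  r
}

#' Golden-spiral unit-sphere quadrature points
#'
#' @param n number of points.
#' @return an `n x 3` matrix of unit vectors.
#' @export
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Bonded energy terms
#'
#' @param sys a `molecular_system`.
#' @param xyz coordinates (defaults to the system's own).
#' @return named vector `E_bond`, `E_angle`, `E_torsion`, `E_improper`
#'   (kcal/mol).
#' @export
bonded_energy <- function(sys, xyz = sys$xyz) {
  p <- pack_energy(sys, terms = "bonded")
  e <- cpp_energy(xyz, p)
  c(E_bond = e[1], E_angle = e[2], E_torsion = e[3], E_improper = e[4])
}

#' Lennard-Jones and Coulomb energy
#'
#' Pairwise sums over all non-excluded pairs with AMBER 1-4 scaling and the
#' offset-regularized distances; no cutoffs.
#'
#' @inheritParams bonded_energy
#' @param params a [solvent_params()].
#' @return named vector `E_LJ`, `E_Coulomb` (kcal/mol).
#' @export
lj_coulomb_energy <- function(sys, xyz = sys$xyz, params = solvent_params()) {
  p <- pack_energy(sys, params, terms = "nonbonded")
  e <- cpp_energy(xyz, p)
  c(E_LJ = e[5], E_Coulomb = e[6])
}

#' Effective Born radii (OBC-II pairwise descreening)
#'
#' An isolated atom's Born radius equals its offset intrinsic radius; radii
#' grow as an atom is buried.  Descreening integrals use the
#' offset-regularized distances.
#'
#' @inheritParams lj_coulomb_energy
#' @return per-atom Born radii in Angstrom.
#' @export
born_radii <- function(sys, xyz = sys$xyz, params = solvent_params()) {
  if (any(sys$gb_radius <= 0)) stop("nonpositive intrinsic GB radius")
  rho <- sys$gb_radius - params$gb_offset
  if (any(rho <= 0)) stop("intrinsic GB radius below the radius offset")
  scr <- params$gb_screen[sys$atoms$element]
  scr[is.na(scr)] <- params$gb_screen_default
  cpp_born_radii(xyz, rho, unname(scr * rho), sys$gb_radius, params$delta,
                 params$gb_alpha, params$gb_beta, params$gb_gamma)
}

#' Generalized-Born polar solvation energy
#'
#' Still's pairwise form with self terms:
#' `dG = -(k_e/2) (1/eps_p - 1/eps_w) sum_ij q_i q_j / f_GB`,
#' `f_GB = sqrt(r'^2 + B_i B_j exp(-r'^2 / (4 B_i B_j)))`, with
#' `f_GB = B_i` on the diagonal.  Nonpositive for any nonzero charges when
#' `eps_w > eps_p`.
#'
#' @param charge per-atom charges (e).
#' @param xyz coordinates.
#' @param born per-atom Born radii (A), positive.
#' @param params a [solvent_params()].
#' @return energy in kcal/mol.
#' @export
gb_polar_energy <- function(charge, xyz, born, params = solvent_params()) {
  if (any(born <= 0)) stop("nonpositive Born radius")
  pref <- -0.5 * params$k_e * (1 / params$eps_p - 1 / params$eps_w)
  cpp_gb_energy(as.matrix(xyz), charge, born, params$delta, pref)
}

#' Solvent-accessible surface area and nonpolar solvation energy
#'
#' Shrake-Rupley quadrature on spheres of (atom radius + probe); atom radii
#' default to the Lennard-Jones minimum positions, `2^(1/6) sigma / 2`.
#' Atoms with nonpositive radius carry no area and do not occlude others.
#'
#' @inheritParams lj_coulomb_energy
#' @param radii optional explicit per-atom radii (A), overriding the
#'   LJ-derived values.
#' @return list with `per_atom` (A^2), `total` (A^2) and `E_nonpolar`
#'   (kcal/mol, `gamma * total` with gamma converted from cal to kcal).
#' @export
sasa_nonpolar <- function(sys, xyz = sys$xyz, params = solvent_params(),
                          radii = NULL) {
  if (is.null(radii)) radii <- sasa_radii(sys)
  if (any(radii < 0)) stop("negative SASA radius")
  per <- cpp_sasa(as.matrix(xyz), radii, params$probe,
                  sphere_points(params$sasa_points))
  tot <- sum(per)
  list(per_atom = per, total = tot,
       E_nonpolar = params$gamma / 1000 * tot)
}

#' Total potential energy with per-term breakdown
#'
#' @inheritParams lj_coulomb_energy
#' @param restraint optional Q-restraint, a list with elements `Q0` (wall
#'   position) and `k` (kcal/mol per unit Q^2); requires `contacts`.
#' @param contacts a [define_native_contacts()] set, needed only for the
#'   restraint term.
#' @param terms which energy groups to evaluate; defaults to all.
#' @param pack optional precomputed [pack_energy()] result.
#' @return an `energy_breakdown`: named numeric vector of the components
#'   and their sum `E_total` (kcal/mol).
#' @export
total_energy <- function(sys, xyz = sys$xyz, params = solvent_params(),
                         restraint = NULL, contacts = NULL,
                         terms = c("bonded", "nonbonded", "gb", "sasa"),
                         pack = NULL) {
  if (is.null(pack)) pack <- pack_energy(sys, params, terms)
  e <- cpp_energy(as.matrix(xyz), pack)
  er <- 0
  if (!is.null(restraint)) {
    if (is.null(contacts)) stop("restraint requires a native contact set")
    q <- compute_q(xyz, contacts)
    er <- q_restraint_energy(q, restraint$Q0, restraint$k)
  }
  out <- c(E_bond = e[1], E_angle = e[2], E_torsion = e[3],
           E_improper = e[4], E_LJ = e[5], E_Coulomb = e[6], E_GB = e[7],
           E_nonpolar = e[8], E_restraint = er)
  out <- c(out, E_total = sum(out))
  class(out) <- "energy_breakdown"
  out
}

#' @export
print.energy_breakdown <- function(x, ...) {
  y <- unclass(x)
  cat("Energy breakdown (kcal/mol):\n")
  for (nm in names(y)) cat(sprintf("  %-12s %12.4f\n", nm, y[[nm]]))
  invisible(x)
}
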