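#' Implicit-solvent and physical-constant parameters
#'
#' Bundles every tunable of the energy model: the dielectric constants of
#' the protein interior and of water, the nonpolar surface tension, the
#' solvent probe radius, the distance-offset regularization applied to all
#' interatomic distances entering the Coulomb, Lennard-Jones and
#' generalized-Born terms, and the generalized-Born flavor parameters
#' (OBC-II pairwise descreening).
#'
#' @param eps_p protein (solute) dielectric constant, dimensionless.
#' @param eps_w water dielectric constant, dimensionless.
#' @param gamma surface tension of the nonpolar solvation term, in
#'   cal/mol/A^2 (converted to kcal internally).
#' @param probe solvent probe radius in Angstrom.
#' @param delta constant offset in Angstrom added to every interatomic
#'   distance in the Coulomb, Lennard-Jones and GB terms; keeps the energy
#'   finite even at exact atomic overlap.
#' @param k_e Coulomb constant in kcal*A/mol/e^2.
#' @param k_B Boltzmann constant in kcal/mol/K.
#' @param gb_offset intrinsic-radius offset (A) subtracted from the GB
#'   intrinsic radii before descreening.
#' @param gb_alpha,gb_beta,gb_gamma OBC-II tanh-rescaling coefficients.
#' @param gb_screen named vector of per-element descreening scale factors;
#'   elements not listed fall back to `gb_screen_default`.
#' @param gb_screen_default fallback descreening scale factor.
#' @param sasa_points number of sphere quadrature points per atom for the
#'   Shrake-Rupley surface-area calculation.
#' @param scale_lj14,scale_coul14 scaling applied to 1-4 Lennard-Jones and
#'   Coulomb interactions (AMBER convention).
#'
#' @return An object of class `solvent_params` (a named list).
#' @export
solvent_params <- function(eps_p = 1, eps_w = 80, gamma = 5.42,
                           probe = 1.4, delta = 0.001,
                           k_e = 332.0636, k_B = 1.9872041e-3,
                           gb_offset = 0.009,
                           gb_alpha = 1.0, gb_beta = 0.8, gb_gamma = 4.85,
                           gb_screen = c(H = 0.85, C = 0.72, N = 0.79,
                                         O = 0.85, S = 0.96, P = 0.86),
                           gb_screen_default = 0.8,
                           sasa_points = 960,
                           scale_lj14 = 0.5, scale_coul14 = 1 / 1.2) {
  stopifnot(eps_w > eps_p, eps_p >= 1, gamma >= 0, delta > 0, probe >= 0,
            sasa_points >= 12)
  structure(list(eps_p = eps_p, eps_w = eps_w, gamma = gamma, probe = probe,
                 delta = delta, k_e = k_e, k_B = k_B, gb_offset = gb_offset,
                 gb_alpha = gb_alpha, gb_beta = gb_beta, gb_gamma = gb_gamma,
                 gb_screen = gb_screen,
                 gb_screen_default = gb_screen_default,
                 sasa_points = sasa_points, scale_lj14 = scale_lj14,
                 scale_coul14 = scale_coul14),
            class = "solvent_params")
}

#' Offset-regularized interatomic distance
#'
#' Adds the constant offset `delta` (default 0.001 A) to a distance before
#' it enters the Coulomb, Lennard-Jones or GB terms, so that clashing atoms
#' produce large but finite energies.
#'
#' @param r distance(s) in Angstrom, `>= 0`.
#' @param params a [solvent_params()] object.
#' @return the offset distance `delta + r`, strictly positive.
#' @export
effective_distance <- function(r, params = solvent_params()) {
  if (any(r < 0)) stop("negative distance")
  r + params$delta
}
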