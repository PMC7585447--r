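# Synthetic test systems: a parameterized polyalanine-like peptide built
# from ideal internal coordinates, a one-dihedral toy with an analytic
# Boltzmann distribution, and analytic micro-systems (single ion, charge
# pair).  These stand in for externally parameterized structures so that
# every simulation and analysis path runs without downloads.

# run expr with a private RNG seed, restoring the caller's RNG state
with_private_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# NeRF internal-coordinate placement: position X bonded to C with
# |X-C| = bond, angle(X,C,B) = ang and torsion(X,C,B,A) = tor  (rad).
place_atom <- function(A, B, C, bond, ang, tor) {
  u <- C - B; u <- u / sqrt(sum(u^2))
  ab <- B - A
  n <- c(ab[2] * u[3] - ab[3] * u[2],
         ab[3] * u[1] - ab[1] * u[3],
         ab[1] * u[2] - ab[2] * u[1])
  n <- n / sqrt(sum(n^2))
  v <- c(n[2] * u[3] - n[3] * u[2],
         n[3] * u[1] - n[1] * u[3],
         n[1] * u[2] - n[2] * u[1])
  C + bond * (-cos(ang) * u + sin(ang) * (cos(tor) * v + sin(tor) * n))
}

#' Torsion angle from coordinates
#'
#' @param xyz coordinate matrix (rows = atoms).
#' @param i,j,k,l 1-based atom indices defining the torsion.
#' @return angle in radians, in `(-pi, pi]`.
#' @export
torsion_angle <- function(xyz, i, j, k, l) {
  cpp_dihedral_angle(xyz, i - 1L, j - 1L, k - 1L, l - 1L)
}

.fix_lj <- list(H = c(2.50, 0.016), C = c(3.40, 0.109),
                N = c(3.25, 0.170), O = c(2.96, 0.210))
.fix_gb <- c(H = 1.2, C = 1.7, N = 1.55, O = 1.5, S = 1.8)

#' Generate a synthetic parameterized peptide
#'
#' Builds a polyalanine-like chain with hydrogens from ideal internal
#' coordinates (extended backbone with a small seeded jitter on phi/psi),
#' assigns self-consistent bonded parameters (bond and angle equilibrium
#' values equal the built geometry, so the harmonic terms are exactly zero
#' at the generated conformation), neutral per-residue charges, per-element
#' Lennard-Jones and GB radii, and the 1-2/1-3 exclusion and 1-4 pair sets.
#'
#' Each residue contributes 10 atoms (N, H, CA, HA, CB, HB1-3, C, O); the
#' chain carries one extra amino hydrogen at the N terminus and an OXT at
#' the C terminus, so the atom count is `10 * n_residues + 2`.
#'
#' @param n_residues number of residues, `>= 1`.
#' @param seed integer seed controlling the backbone jitter; the same seed
#'   reproduces the system bit for bit.
#' @return list with elements `system` (a [molecular_system()]) and
#'   `dihedrals` (its [build_rotatable_dihedrals()] set).
#' @export
generate_fixture_peptide <- function(n_residues, seed = 1) {
  if (n_residues < 1) stop("n_residues must be >= 1")
  with_private_seed(seed, .build_fixture_peptide(n_residues))
}

.build_fixture_peptide <- function(nres) {
  deg <- pi / 180
  phi <- pi + runif(nres, -0.35, 0.35)   # near-extended backbone
  psi <- pi + runif(nres, -0.35, 0.35)

  nat <- 10L * nres + 2L
  name <- character(nat); elem <- character(nat)
  resid <- integer(nat); xyz <- matrix(NA_real_, nat, 3)
  bonds <- list(); angles <- list(); dihs <- list()
  idx <- 0L
  add_atom <- function(nm, el, ri, pos) {
    idx <<- idx + 1L
    name[idx] <<- nm; elem[idx] <<- el; resid[idx] <<- ri
    xyz[idx, ] <<- pos
    idx
  }
  AT <- function(ri, nm) which(name[seq_len(idx)] == nm &
                               resid[seq_len(idx)] == ri)[1]

  bl <- c(NCA = 1.458, CAC = 1.525, CN = 1.329, CO = 1.229, NH = 1.010,
          CH = 1.090, CACB = 1.526, COXT = 1.250)
  an <- c(CNCA = 121.7, NCAC = 111.2, CACN = 116.6, CACO = 120.8,
          CNH = 119.5, NCAH = 109.5, NCACB = 110.5, CACBH = 109.5,
          CANH = 118.0) * deg

  for (r in seq_len(nres)) {
    if (r == 1L) {
      iN <- add_atom("N", "N", r, c(0, 0, 0))
      iCA <- add_atom("CA", "C", r, c(bl["NCA"], 0, 0))
      iC <- add_atom("C", "C", r,
                     c(bl["NCA"] - bl["CAC"] * cos(an["NCAC"]),
                       bl["CAC"] * sin(an["NCAC"]), 0))
      # two amino hydrogens on the N terminus
      iH <- add_atom("H", "H", r,
                     place_atom(xyz[iC, ], xyz[iCA, ], xyz[iN, ],
                                bl["NH"], an["CANH"], 60 * deg))
      iH2 <- add_atom("H2", "H", r,
                      place_atom(xyz[iC, ], xyz[iCA, ], xyz[iN, ],
                                 bl["NH"], an["CANH"], -60 * deg))
      bonds <- c(bonds, list(c(iN, iH), c(iN, iH2)))
      angles <- c(angles, list(c(iCA, iN, iH), c(iCA, iN, iH2),
                               c(iH, iN, iH2)))
    } else {
      iCp <- AT(r - 1L, "C"); iCAp <- AT(r - 1L, "CA")
      iNp <- AT(r - 1L, "N")
      iN <- add_atom("N", "N", r,
                     place_atom(xyz[iNp, ], xyz[iCAp, ], xyz[iCp, ],
                                bl["CN"], an["CACN"], psi[r - 1L]))
      iH <- add_atom("H", "H", r,
                     place_atom(xyz[iCAp, ], xyz[iCp, ], xyz[iN, ],
                                bl["NH"], an["CNH"], 0))
      iCA <- add_atom("CA", "C", r,
                      place_atom(xyz[iCAp, ], xyz[iCp, ], xyz[iN, ],
                                 bl["NCA"], an["CNCA"], pi))
      iC <- add_atom("C", "C", r,
                     place_atom(xyz[iCp, ], xyz[iN, ], xyz[iCA, ],
                                bl["CAC"], an["NCAC"], phi[r]))
      bonds <- c(bonds, list(c(iCp, iN), c(iN, iH)))
      angles <- c(angles, list(c(iCAp, iCp, iN), c(iCp, iN, iH),
                               c(iCp, iN, iCA), c(iH, iN, iCA)))
      # amide planarity and backbone torsions along the new bonds
      dihs <- c(dihs,
                list(c(iCAp, iCp, iN, iCA, 2.5, 2, pi, 0),   # omega
                     c(iCp, iN, iCA, iC, 0.20, 3, 0, 0),     # phi
                     c(iNp, iCAp, iCp, iN, 0.20, 3, 0, 0)))  # psi
    }
    # substituents on CA: torsions measured from the preceding C where it
    # exists, otherwise from this residue's own C (residue 1)
    refA <- if (r == 1L) iC else AT(r - 1L, "C")
    torHA <- if (r == 1L) -120 * deg else phi[r] - 120 * deg
    torCB <- if (r == 1L) 120 * deg else phi[r] + 120 * deg
    iHA <- add_atom("HA", "H", r,
                    place_atom(xyz[refA, ], xyz[iN, ], xyz[iCA, ],
                               bl["CH"], an["NCAH"], torHA))
    iCB <- add_atom("CB", "C", r,
                    place_atom(xyz[refA, ], xyz[iN, ], xyz[iCA, ],
                               bl["CACB"], an["NCACB"], torCB))
    for (h in 1:3) {
      iHB <- add_atom(paste0("HB", h), "H", r,
                      place_atom(xyz[iN, ], xyz[iCA, ], xyz[iCB, ],
                                 bl["CH"], an["CACBH"],
                                 (h - 2) * 120 * deg + 60 * deg))
      bonds <- c(bonds, list(c(iCB, iHB)))
      angles <- c(angles, list(c(iCA, iCB, iHB)))
    }
    angles <- c(angles, list(c(AT(r, "HB1"), iCB, AT(r, "HB2")),
                             c(AT(r, "HB1"), iCB, AT(r, "HB3")),
                             c(AT(r, "HB2"), iCB, AT(r, "HB3"))))
    dihs <- c(dihs, list(c(iN, iCA, iCB, AT(r, "HB1"), 0.16, 3, 0, 0)))
    iO <- add_atom("O", "O", r,
                   place_atom(xyz[iN, ], xyz[iCA, ], xyz[iC, ],
                              bl["CO"], an["CACO"], psi[r] + pi))
    bonds <- c(bonds, list(c(iN, iCA), c(iCA, iC), c(iCA, iHA),
                           c(iCA, iCB), c(iC, iO)))
    angles <- c(angles, list(c(iN, iCA, iC), c(iN, iCA, iHA),
                             c(iN, iCA, iCB), c(iHA, iCA, iC),
                             c(iHA, iCA, iCB), c(iCB, iCA, iC),
                             c(iCA, iC, iO)))
    dihs <- c(dihs, list(c(iN, iCA, iC, iO, 0, 2, pi, 1)))  # carbonyl improper
    if (r == nres) {
      iOXT <- add_atom("OXT", "O", r,
                       place_atom(xyz[iN, ], xyz[iCA, ], xyz[iC, ],
                                  bl["COXT"], an["CACO"], psi[r]))
      bonds <- c(bonds, list(c(iC, iOXT)))
      angles <- c(angles, list(c(iCA, iC, iOXT), c(iO, iC, iOXT)))
    }
  }

  name <- name[seq_len(idx)]; elem <- elem[seq_len(idx)]
  resid <- resid[seq_len(idx)]; xyz <- xyz[seq_len(idx), , drop = FALSE]

  kb_of <- function(i, j) {
    e <- sort(c(elem[i], elem[j]))
    if (e[1] == "H") 340 else if (all(e == c("C", "O"))) 570
    else if (all(e == c("C", "N"))) 430 else 310
  }
  bm <- do.call(rbind, bonds)
  bdf <- data.frame(ai = bm[, 1], aj = bm[, 2],
                    kb = mapply(kb_of, bm[, 1], bm[, 2]),
                    r0 = sqrt(rowSums((xyz[bm[, 1], , drop = FALSE] -
                                       xyz[bm[, 2], , drop = FALSE])^2)))
  am <- do.call(rbind, angles)
  th0 <- vapply(seq_len(nrow(am)), function(m) {
    u <- xyz[am[m, 1], ] - xyz[am[m, 2], ]
    v <- xyz[am[m, 3], ] - xyz[am[m, 2], ]
    acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2)))
  }, numeric(1))
  adf <- data.frame(ai = am[, 1], aj = am[, 2], ak = am[, 3],
                    kth = 50, th0 = th0)
  dm <- do.call(rbind, dihs)
  ddf <- data.frame(ai = dm[, 1], aj = dm[, 2], ak = dm[, 3], al = dm[, 4],
                    kphi = dm[, 5], per = dm[, 6], phase = dm[, 7],
                    improper = dm[, 8])
  # improper on the carbonyl carbon gets a real force constant
  ddf$kphi[ddf$improper == 1] <- 10.5

  qres <- c(N = -0.40, H = 0.25, CA = 0.05, HA = 0.05, CB = -0.30,
            HB1 = 0.10, HB2 = 0.10, HB3 = 0.10, C = 0.65, O = -0.60,
            H2 = 0.30, OXT = -0.30)
  charge <- unname(qres[name])
  lj <- t(vapply(elem, function(e) .fix_lj[[e]], numeric(2)))
  gbr <- unname(.fix_gb[elem])

  ep <- derive_excl_14(bdf, idx)
  atoms <- data.frame(name = name, element = elem, resname = "ALA",
                      resid = resid, chain = "A",
                      stringsAsFactors = FALSE)
  sys <- molecular_system(atoms, xyz, charge = charge,
                          lj_sigma = lj[, 1], lj_eps = lj[, 2],
                          gb_radius = gbr, bonds = bdf, angles = adf,
                          dihedrals = ddf, exclusions = ep$exclusions,
                          pairs14 = ep$pairs14)
  list(system = sys, dihedrals = build_rotatable_dihedrals(sys))
}

# 1-2/1-3 exclusions and 1-4 pairs from the bond list
derive_excl_14 <- function(bonds, n) {
  adj <- vector("list", n)
  for (m in seq_len(nrow(bonds))) {
    i <- bonds$ai[m]; j <- bonds$aj[m]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  ex <- list(); p14 <- list()
  for (i in seq_len(n)) {
    n1 <- adj[[i]]
    n2 <- setdiff(unique(unlist(adj[n1])), c(i, n1))
    n3 <- setdiff(unique(unlist(adj[n2])), c(i, n1, n2))
    for (j in n1[n1 > i]) ex[[length(ex) + 1L]] <- c(i, j)
    for (j in n2[n2 > i]) ex[[length(ex) + 1L]] <- c(i, j)
    for (j in n3[n3 > i]) p14[[length(p14) + 1L]] <- c(i, j)
  }
  list(exclusions = do.call(rbind, ex), pairs14 = do.call(rbind, p14))
}

#' One-dihedral toy system
#'
#' Four atoms in a chain with a single rotatable central bond and a single
#' proper torsion term `V(phi) = kphi * (1 + cos(phi))`, no charges and no
#' Lennard-Jones interactions.  Its Boltzmann distribution over phi is
#' analytic, which makes it the reference system for sampling-correctness
#' checks.
#'
#' @param kphi torsion force constant in kcal/mol.
#' @return list with `system` and `dihedrals` as for
#'   [generate_fixture_peptide()].
#' @export
generate_toy_dihedral_system <- function(kphi = 1) {
  b <- 1.5; th <- 109.5 * pi / 180
  x3 <- c(b - b * cos(th), b * sin(th), 0)
  x4 <- place_atom(c(0, 0, 0), c(b, 0, 0), x3, b, th, pi / 2)
  atoms <- data.frame(name = paste0("X", 1:4), element = "C",
                      resname = "TOY", resid = 1L, chain = "A",
                      stringsAsFactors = FALSE)
  xyz <- rbind(c(0, 0, 0), c(b, 0, 0), x3, x4)
  bonds <- data.frame(ai = 1:3, aj = 2:4, kb = 300, r0 = b)
  angles <- data.frame(ai = c(1, 2), aj = c(2, 3), ak = c(3, 4),
                       kth = 50, th0 = th)
  dihs <- data.frame(ai = 1, aj = 2, ak = 3, al = 4, kphi = kphi,
                     per = 1, phase = 0, improper = 0)
  ep <- derive_excl_14(bonds, 4L)
  sys <- molecular_system(atoms, xyz, bonds = bonds, angles = angles,
                          dihedrals = dihs, exclusions = ep$exclusions,
                          pairs14 = ep$pairs14)
  list(system = sys, dihedrals = build_rotatable_dihedrals(sys))
}

#' Analytic micro-systems
#'
#' `generate_single_ion()` builds a one-atom system (charge `q`, intrinsic
#' GB radius chosen so that the effective Born radius equals `born_radius`
#' under the configured intrinsic-radius offset); its GB energy has the
#' closed Born form.  `generate_ion_pair()` builds two point charges at
#' separation `r` on the x axis.
#'
#' @param q charge(s) in e.
#' @param born_radius desired effective Born radius of the isolated ion (A).
#' @param r separation in A.
#' @param params a [solvent_params()] (supplies the intrinsic-radius offset).
#' @return a `molecular_system`.
#' @export
generate_single_ion <- function(q = 1, born_radius = 2,
                                params = solvent_params()) {
  atoms <- data.frame(name = "ION", element = "X", resname = "ION",
                      resid = 1L, chain = "A", stringsAsFactors = FALSE)
  molecular_system(atoms, matrix(0, 1, 3), charge = q,
                   gb_radius = born_radius + params$gb_offset)
}

#' @rdname generate_single_ion
#' @export
generate_ion_pair <- function(q = c(1, 1), r = 3, born_radius = 2,
                              params = solvent_params()) {
  atoms <- data.frame(name = c("I1", "I2"), element = "X", resname = "ION",
                      resid = 1:2, chain = "A", stringsAsFactors = FALSE)
  molecular_system(atoms, rbind(c(0, 0, 0), c(r, 0, 0)), charge = q,
                   gb_radius = born_radius + params$gb_offset)
}
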