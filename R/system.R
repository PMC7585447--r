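#' Construct a molecular system
#'
#' The central container: atom records, coordinates, partial charges,
#' per-atom Lennard-Jones and generalized-Born parameters, the bonded terms
#' (bonds, angles, proper/improper torsions), the 1-2/1-3 exclusion set and
#' the 1-4 pair set.  Internal units are kcal/mol, Angstrom, radian and
#' elementary charge throughout.
#'
#' @param atoms data.frame with columns `name`, `element`, `resname`,
#'   `resid` (1-based residue number as in the source file), `chain`.
#' @param xyz numeric matrix, one row per atom, columns x/y/z in Angstrom.
#' @param charge partial charges in e (default all zero).
#' @param lj_sigma,lj_eps per-atom Lennard-Jones sigma (A) and epsilon
#'   (kcal/mol).
#' @param gb_radius per-atom intrinsic GB radius (A).
#' @param bonds data.frame `ai, aj, kb, r0` with E = kb*(r-r0)^2.
#' @param angles data.frame `ai, aj, ak, kth, th0` (th0 in rad) with
#'   E = kth*(theta-th0)^2.
#' @param dihedrals data.frame `ai, aj, ak, al, kphi, per, phase, improper`
#'   with E = kphi*(1+cos(per*phi-phase)), phase in rad.
#' @param exclusions two-column matrix of 1-2/1-3 excluded atom pairs.
#' @param pairs14 two-column matrix of 1-4 pairs (scaled nonbonded).
#' @return An object of class `molecular_system`.
#' @export
molecular_system <- function(atoms, xyz, charge = NULL, lj_sigma = NULL,
                             lj_eps = NULL, gb_radius = NULL,
                             bonds = NULL, angles = NULL, dihedrals = NULL,
                             exclusions = NULL, pairs14 = NULL) {
  n <- nrow(atoms)
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  if (nrow(xyz) != n || ncol(xyz) != 3)
    stop("coordinate count does not match atom count")
  peratom <- function(x, what) {
    if (is.null(x)) return(rep(0, n))
    x <- as.numeric(x)
    if (length(x) == 1) return(rep(x, n))
    if (length(x) != n)
      stop(what, " must have length 1 or ", n, ", got ", length(x))
    x
  }
  sys <- structure(list(
    atoms = atoms, xyz = xyz,
    charge = peratom(charge, "charge"),
    lj_sigma = peratom(lj_sigma, "lj_sigma"),
    lj_eps = peratom(lj_eps, "lj_eps"),
    gb_radius = peratom(gb_radius, "gb_radius"),
    bonds = .empty_df(bonds, c("ai", "aj", "kb", "r0")),
    angles = .empty_df(angles, c("ai", "aj", "ak", "kth", "th0")),
    dihedrals = .empty_df(dihedrals, c("ai", "aj", "ak", "al", "kphi",
                                       "per", "phase", "improper")),
    exclusions = .pair_mat(exclusions),
    pairs14 = .pair_mat(pairs14)
  ), class = "molecular_system")
  validate_system(sys)
  sys
}

.empty_df <- function(x, cols) {
  if (is.null(x)) {
    x <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
  }
  x <- as.data.frame(x)
  if (!all(cols %in% names(x))) stop("missing columns: ",
                                     paste(setdiff(cols, names(x)),
                                           collapse = ", "))
  x[cols]
}

.pair_mat <- function(x) {
  if (is.null(x) || NROW(x) == 0)
    return(matrix(integer(0), ncol = 2))
  x <- as.matrix(x)
  storage.mode(x) <- "integer"
  # canonical order: smaller index first, unique rows
  sw <- x[, 1] > x[, 2]
  x[sw, ] <- x[sw, c(2, 1), drop = FALSE]
  unique(x)
}

#' Validate a molecular system's invariants
#'
#' Checks coordinate/atom count agreement, index validity of every bonded
#' term, finiteness of charges and parameters, and the disjointness of the
#' 1-4 pair set from the exclusion set.
#'
#' @param sys a `molecular_system`.
#' @return `sys`, invisibly; errors describe the first violation found.
#' @export
validate_system <- function(sys) {
  n <- nrow(sys$atoms)
  if (nrow(sys$xyz) != n) stop("coordinate count != atom count")
  idx <- c(sys$bonds$ai, sys$bonds$aj, sys$angles$ai, sys$angles$aj,
           sys$angles$ak, sys$dihedrals$ai, sys$dihedrals$aj,
           sys$dihedrals$ak, sys$dihedrals$al,
           as.vector(sys$exclusions), as.vector(sys$pairs14))
  if (length(idx) && (min(idx) < 1 || max(idx) > n))
    stop("bonded-term atom index out of range")
  if (!all(is.finite(sys$xyz))) stop("non-finite coordinates")
  for (f in c("charge", "lj_sigma", "lj_eps", "gb_radius"))
    if (!all(is.finite(sys[[f]]))) stop("non-finite ", f)
  if (nrow(sys$pairs14) && nrow(sys$exclusions)) {
    k14 <- paste(sys$pairs14[, 1], sys$pairs14[, 2])
    kex <- paste(sys$exclusions[, 1], sys$exclusions[, 2])
    bad <- intersect(k14, kex)
    if (length(bad))
      stop("pair listed both as 1-4 and as exclusion: ", bad[1])
  }
  invisible(sys)
}

#' @export
print.molecular_system <- function(x, ...) {
  cat("Molecular system:", nrow(x$atoms), "atoms,",
      length(unique(x$atoms$resid)), "residues\n")
  cat("  bonds:", nrow(x$bonds), " angles:", nrow(x$angles),
      " torsions:", nrow(x$dihedrals), "\n")
  cat("  exclusions:", nrow(x$exclusions), " 1-4 pairs:",
      nrow(x$pairs14), "\n")
  cat("  net charge:", format(sum(x$charge), digits = 4), "e\n")
  invisible(x)
}

# adjacency list of the bond graph
bond_adjacency <- function(sys) {
  n <- nrow(sys$atoms)
  adj <- vector("list", n)
  for (m in seq_len(nrow(sys$bonds))) {
    i <- sys$bonds$ai[m]; j <- sys$bonds$aj[m]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

# connected component containing `start`, optionally with edge from-to removed
graph_component <- function(adj, start, drop_edge = NULL) {
  n <- length(adj)
  seen <- logical(n)
  stack <- start
  seen[start] <- TRUE
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    for (w in adj[[v]]) {
      if (!is.null(drop_edge) &&
          ((v == drop_edge[1] && w == drop_edge[2]) ||
           (v == drop_edge[2] && w == drop_edge[1]))) next
      if (!seen[w]) { seen[w] <- TRUE; stack <- c(stack, w) }
    }
  }
  which(seen)
}

#' Select atoms from a system
#'
#' @param sys a `molecular_system`.
#' @param selection one of `"all"`, `"heavy"` (non-hydrogen), `"backbone"`
#'   (N, CA, C, O) or `"calpha"`.
#' @return integer vector of atom indices.
#' @export
atom_select <- function(sys, selection = c("all", "heavy", "backbone",
                                           "calpha")) {
  selection <- match.arg(selection)
  a <- sys$atoms
  switch(selection,
         all = seq_len(nrow(a)),
         heavy = which(a$element != "H"),
         backbone = which(a$name %in% c("N", "CA", "C", "O")),
         calpha = which(a$name == "CA"))
}
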