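# Topology input.  Two ASCII dialects are accepted:
#
# 1. A documented subset of the GROMACS topology format (the directives
#    [defaults], [atomtypes], [moleculetype], [atoms], [bonds], [pairs],
#    [angles], [dihedrals], [exclusions], [system], [molecules]), with the
#    GROMACS units (nm, kJ/mol, degrees) converted to the internal
#    kcal/mol / Angstrom / radian convention.  GROMACS harmonic constants
#    (E = k/2 (b-b0)^2) are halved into the internal E = k (r-r0)^2 form.
#    Include directives are not resolved: files must be self-contained.
#
# 2. A flat self-describing dialect (first line `#foldmc-topology`) already
#    in internal units, used by the fixture generator; its [atoms] rows
#    carry sigma/epsilon/GB radius explicitly.
#
# Exclusions (1-2, 1-3) are always derived from the bond graph and merged
# with any explicit [exclusions]; [pairs] provides the 1-4 set.  GB radii
# default per element when the file does not carry them.

KJ2KCAL <- 1 / 4.184
NM2A <- 10

.default_gb_radius <- c(H = 1.2, C = 1.7, N = 1.55, O = 1.5, S = 1.8,
                        P = 1.85)

#' Read a force-field topology
#'
#' @param path topology file (GROMACS subset or flat dialect, see the
#'   package vignette).
#' @return a `topology` list with per-atom `charge`, `lj_sigma`, `lj_eps`,
#'   `gb_radius`, atom `name`/`resname`/`resid`, and `bonds`, `angles`,
#'   `dihedrals`, `pairs14`, `exclusions` tables in internal units.
#' @export
read_topology <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  flat <- length(lines) > 0 && grepl("^#foldmc-topology", lines[1])
  lines <- sub("[;#].*$", "", lines)
  lines <- trimws(lines)
  keep <- lines != ""
  lineno <- which(keep)
  lines <- lines[keep]

  known <- c("defaults", "atomtypes", "moleculetype", "atoms", "bonds",
             "pairs", "angles", "dihedrals", "exclusions", "system",
             "molecules")
  section <- NA_character_
  rows <- list()
  for (t in seq_along(lines)) {
    ln <- lines[t]
    if (grepl("^\\[", ln)) {
      sec <- trimws(gsub("\\[|\\]", "", ln))
      if (!(sec %in% known))
        stop("unknown directive [", sec, "] at line ", lineno[t])
      section <- sec
      next
    }
    if (is.na(section))
      stop("content before any [section] at line ", lineno[t])
    rows[[section]] <- c(rows[[section]], list(strsplit(ln, "\\s+")[[1]]))
  }
  if (is.null(rows$atoms)) stop("topology has no [atoms] section")

  if (flat) .parse_flat_topology(rows) else .parse_gmx_topology(rows)
}

.num <- function(x) {
  v <- suppressWarnings(as.numeric(x))
  if (any(is.na(v))) stop("non-numeric field in topology: ",
                          paste(x, collapse = " "))
  v
}

.elem_from_name <- function(nm) {
  e <- toupper(substr(gsub("^[0-9]+", "", nm), 1, 1))
  e
}

.parse_gmx_topology <- function(rows) {
  # atomtypes: name ... sigma epsilon (last two numeric columns, GROMACS
  # units nm / kJ/mol)
  at_sigma <- numeric(0); at_eps <- numeric(0)
  for (r in rows$atomtypes) {
    k <- length(r)
    if (k < 3) stop("atomtypes line too short")
    at_sigma[r[1]] <- .num(r[k - 1]) * NM2A
    at_eps[r[1]] <- .num(r[k]) * KJ2KCAL
  }
  nat <- length(rows$atoms)
  name <- character(nat); type <- character(nat)
  resname <- character(nat); resid <- integer(nat); charge <- numeric(nat)
  for (i in seq_len(nat)) {
    r <- rows$atoms[[i]]
    if (length(r) < 7) stop("atoms line needs >= 7 fields (nr type resnr ",
                            "residue atom cgnr charge)")
    if (.num(r[1]) != i) stop("atom numbering must be sequential at atom ",
                              r[1])
    type[i] <- r[2]; resid[i] <- as.integer(.num(r[3]))
    resname[i] <- r[4]; name[i] <- r[5]; charge[i] <- .num(r[7])
  }
  missing_t <- setdiff(unique(type), names(at_sigma))
  if (length(missing_t) && length(rows$atomtypes))
    stop("missing [atomtypes] parameters for: ",
         paste(missing_t, collapse = ", "))
  if (!length(rows$atomtypes)) { at_sigma[type] <- 0; at_eps[type] <- 0 }

  # GROMACS line layouts: bonds "ai aj funct b0 kb", angles
  # "ai aj ak funct th0 kth", dihedrals "ai aj ak al funct phi0 k mult"
  bonds <- .gmx_rows(rows$bonds, 5, 4, function(r)
    c(.num(r[1]), .num(r[2]),
      .num(r[5]) * KJ2KCAL / NM2A^2 / 2, .num(r[4]) * NM2A))
  colnames(bonds) <- c("ai", "aj", "kb", "r0")
  angles <- .gmx_rows(rows$angles, 6, 5, function(r)
    c(.num(r[1]), .num(r[2]), .num(r[3]),
      .num(r[6]) * KJ2KCAL / 2, .num(r[5]) * pi / 180))
  colnames(angles) <- c("ai", "aj", "ak", "kth", "th0")
  dihedrals <- .gmx_rows(rows$dihedrals, 8, 8, function(r) {
    funct <- .num(r[5])
    if (!funct %in% c(1, 4, 9))
      stop("unsupported dihedral funct ", funct,
           " (periodic 1/9 and improper 4 only)")
    c(.num(r[1]), .num(r[2]), .num(r[3]), .num(r[4]),
      .num(r[7]) * KJ2KCAL, .num(r[8]), .num(r[6]) * pi / 180,
      as.numeric(funct == 4))
  })
  colnames(dihedrals) <- c("ai", "aj", "ak", "al", "kphi", "per", "phase",
                           "improper")
  pairs14 <- .gmx_rows(rows$pairs, 2, 2,
                       function(r) c(.num(r[1]), .num(r[2])))
  excl <- .gmx_rows(rows$exclusions, 2, 2, function(r) {
    v <- .num(r)
    cbind(v[1], v[-1])
  })

  .finish_topology(name, .elem_from_name(name), resname, resid, charge,
                   unname(at_sigma[type]), unname(at_eps[type]),
                   gbr = NULL,
                   as.data.frame(bonds), as.data.frame(angles),
                   as.data.frame(dihedrals), pairs14, excl)
}

.gmx_rows <- function(rr, min_fields, ncol_out, fn) {
  if (is.null(rr)) return(matrix(numeric(0), ncol = ncol_out))
  out <- lapply(rr, function(r) {
    if (length(r) < min_fields)
      stop("topology line too short: ", paste(r, collapse = " "))
    fn(r)
  })
  do.call(rbind, out)
}

.parse_flat_topology <- function(rows) {
  nat <- length(rows$atoms)
  name <- character(nat); elem <- character(nat); resname <- character(nat)
  resid <- integer(nat); charge <- numeric(nat)
  sig <- numeric(nat); eps <- numeric(nat); gbr <- numeric(nat)
  for (i in seq_len(nat)) {
    r <- rows$atoms[[i]]
    if (length(r) < 10)
      stop("flat atoms line needs 10 fields (idx name element resname ",
           "resid chain charge sigma epsilon gbradius)")
    name[i] <- r[2]; elem[i] <- r[3]; resname[i] <- r[4]
    resid[i] <- as.integer(.num(r[5])); charge[i] <- .num(r[7])
    sig[i] <- .num(r[8]); eps[i] <- .num(r[9]); gbr[i] <- .num(r[10])
  }
  g <- function(sec, k) {
    if (is.null(rows[[sec]])) return(matrix(numeric(0), ncol = k))
    do.call(rbind, lapply(rows[[sec]], function(r) .num(r[seq_len(k)])))
  }
  bonds <- g("bonds", 4); colnames(bonds) <- c("ai", "aj", "kb", "r0")
  angles <- g("angles", 5)
  colnames(angles) <- c("ai", "aj", "ak", "kth", "th0")
  dih <- g("dihedrals", 8)
  colnames(dih) <- c("ai", "aj", "ak", "al", "kphi", "per", "phase",
                     "improper")
  .finish_topology(name, elem, resname, resid, charge, sig, eps, gbr,
                   as.data.frame(bonds), as.data.frame(angles),
                   as.data.frame(dih), g("pairs", 2), g("exclusions", 2))
}

.finish_topology <- function(name, elem, resname, resid, charge, sig, eps,
                             gbr, bonds, angles, dihedrals, pairs14, excl) {
  nat <- length(name)
  if (is.null(gbr)) {
    gbr <- .default_gb_radius[elem]
    gbr[is.na(gbr)] <- 1.5
  }
  idx <- c(bonds$ai, bonds$aj, angles$ai, angles$aj, angles$ak,
           dihedrals$ai, dihedrals$aj, dihedrals$ak, dihedrals$al,
           as.vector(pairs14), as.vector(excl))
  if (length(idx) && (min(idx) < 1 || max(idx) > nat))
    stop("interaction references atom index outside [1, ", nat, "]")
  derived <- derive_excl_14(bonds, nat)
  exclusions <- .pair_mat(rbind(derived$exclusions,
                                if (NROW(excl)) excl))
  p14 <- .pair_mat(pairs14)
  if (nrow(p14) && nrow(exclusions)) {
    both <- intersect(paste(p14[, 1], p14[, 2]),
                      paste(exclusions[, 1], exclusions[, 2]))
    if (length(both))
      stop("pair listed both as 1-4 pair and as exclusion: ", both[1])
  }
  structure(list(name = name, element = unname(elem),
                 resname = resname, resid = resid,
                 charge = charge, lj_sigma = unname(sig),
                 lj_eps = unname(eps), gb_radius = unname(gbr),
                 bonds = bonds, angles = angles, dihedrals = dihedrals,
                 pairs14 = p14, exclusions = exclusions),
            class = "topology")
}

#' Combine a structure with a topology
#'
#' @param struct a `molecular_system` from [read_pdb()] (coordinates and
#'   atom records).
#' @param topo a [read_topology()] result; atom order must match the
#'   structure.
#' @return a fully parameterized `molecular_system`.
#' @export
assemble_system <- function(struct, topo) {
  n <- nrow(struct$atoms)
  if (length(topo$name) != n)
    stop("atom count mismatch: structure has ", n, ", topology has ",
         length(topo$name))
  div <- which(struct$atoms$name != topo$name)
  if (length(div))
    stop("atom name mismatch at atom ", div[1], ": structure '",
         struct$atoms$name[div[1]], "' vs topology '", topo$name[div[1]],
         "'")
  molecular_system(struct$atoms, struct$xyz, charge = topo$charge,
                   lj_sigma = topo$lj_sigma, lj_eps = topo$lj_eps,
                   gb_radius = topo$gb_radius, bonds = topo$bonds,
                   angles = topo$angles, dihedrals = topo$dihedrals,
                   exclusions = topo$exclusions, pairs14 = topo$pairs14)
}

#' Write a system as a flat topology file
#'
#' Emits the package's flat self-describing dialect (internal units), the
#' format the fixture generator pairs with [write_pdb()] output.
#'
#' @param sys a `molecular_system`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_topology <- function(sys, path) {
  con <- file(path, "w")
  on.exit(close(con))
  a <- sys$atoms
  writeLines("#foldmc-topology", con)
  writeLines("[atoms]", con)
  writeLines(sprintf("%d %s %s %s %d %s %.6f %.6f %.6f %.6f",
                     seq_len(nrow(a)), a$name, a$element, a$resname,
                     a$resid, ifelse(a$chain == "", "A", a$chain),
                     sys$charge, sys$lj_sigma, sys$lj_eps, sys$gb_radius),
             con)
  b <- sys$bonds
  writeLines("[bonds]", con)
  writeLines(sprintf("%d %d %.6f %.6f", b$ai, b$aj, b$kb, b$r0), con)
  an <- sys$angles
  writeLines("[angles]", con)
  writeLines(sprintf("%d %d %d %.6f %.8f", an$ai, an$aj, an$ak, an$kth,
                     an$th0), con)
  d <- sys$dihedrals
  writeLines("[dihedrals]", con)
  writeLines(sprintf("%d %d %d %d %.6f %g %.8f %d", d$ai, d$aj, d$ak,
                     d$al, d$kphi, d$per, d$phase, d$improper), con)
  if (nrow(sys$pairs14)) {
    writeLines("[pairs]", con)
    writeLines(sprintf("%d %d", sys$pairs14[, 1], sys$pairs14[, 2]), con)
  }
  invisible(path)
}
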