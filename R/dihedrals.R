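#' Enumerate rotatable dihedrals
#'
#' Walks the bond graph and returns every rotatable torsion with the set of
#' atoms moved when it is rotated.  A bond is rotatable when it is not part
#' of a ring, and each side of it carries at least two atoms (so a rotation
#' moves more than a single terminal atom).  Backbone omega (peptide C-N)
#' bonds are never rotatable, and proline phi is excluded.  The downstream
#' set is the connected component on the far side of the bond from the
#' first atom of the chain.
#'
#' @param sys a `molecular_system` with a connected bond graph.
#' @return An object of class `rotatable_dihedrals`: a list of entries with
#'   fields `atoms` (the 4-atom torsion definition), `bond` (the two pivot
#'   atoms), `class` (`"backbone-phi"`, `"backbone-psi"`,
#'   `"sidechain-chi"` or `"other"`) and `downstream` (moved atom indices).
#' @export
build_rotatable_dihedrals <- function(sys) {
  n <- nrow(sys$atoms)
  adj <- bond_adjacency(sys)
  if (length(graph_component(adj, 1L)) != n)
    stop("bond graph is disconnected")
  a <- sys$atoms
  out <- list()
  for (m in seq_len(nrow(sys$bonds))) {
    b <- sys$bonds$ai[m]; cc <- sys$bonds$aj[m]
    side_b <- graph_component(adj, b, drop_edge = c(b, cc))
    if (cc %in% side_b) next                       # ring bond: skip
    side_c <- setdiff(seq_len(n), side_b)
    if (min(length(side_b), length(side_c)) < 2) next  # terminal atom only
    # orient so the chain root (atom 1) stays put
    if (1L %in% side_c) { tmp <- b; b <- cc; cc <- tmp; side_c <- side_b }
    nb <- a$name[b]; nc <- a$name[cc]
    same_res <- a$resid[b] == a$resid[cc]
    cls <- "other"
    if ((nb == "C" && nc == "N") || (nb == "N" && nc == "C")) {
      if (!same_res) next                          # omega: never rotatable
    }
    if (same_res && ((nb == "N" && nc == "CA") || (nb == "CA" && nc == "N"))) {
      if (a$resname[b] == "PRO") next              # proline phi excluded
      # phi requires a preceding backbone C bonded to N
      nn <- if (nb == "N") b else cc
      has_prev <- any(a$name[adj[[nn]]] == "C" &
                      a$resid[adj[[nn]]] == a$resid[nn] - 1L)
      cls <- if (has_prev) "backbone-phi" else "other"
    } else if (same_res &&
               ((nb == "CA" && nc == "C") || (nb == "C" && nc == "CA"))) {
      cls <- "backbone-psi"
    } else if (!(nb %in% c("N", "CA", "C") && nc %in% c("N", "CA", "C"))) {
      cls <- "sidechain-chi"
    }
    out[[length(out) + 1L]] <- list(
      atoms = c(.pick_flank(adj, a, b, cc), b, cc, .pick_flank(adj, a, cc, b)),
      bond = c(b, cc), class = cls, downstream = sort(side_c))
  }
  structure(out, class = "rotatable_dihedrals")
}

# flanking atom for the 4-atom torsion definition: prefer canonical backbone
# neighbors, then heavy atoms, then lowest index
.pick_flank <- function(adj, atoms, at, excl) {
  cand <- setdiff(adj[[at]], excl)
  if (!length(cand)) stop("bond end has no flanking atom")
  canon <- cand[atoms$name[cand] %in% c("N", "CA", "C")]
  if (length(canon)) return(min(canon))
  heavy <- cand[atoms$element[cand] != "H"]
  if (length(heavy)) return(min(heavy))
  min(cand)
}

#' @export
print.rotatable_dihedrals <- function(x, ...) {
  cls <- vapply(x, `[[`, character(1), "class")
  cat("Rotatable dihedrals:", length(x), "\n")
  print(table(cls))
  invisible(x)
}
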