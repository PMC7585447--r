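#' Read a PDB structure
#'
#' Parses ATOM/HETATM records (via bio3d) and returns the requested model
#' of a possibly multi-model file as a `molecular_system` with atom
#' records and coordinates; force-field parameters are attached later from
#' a topology (see [read_topology()] and [assemble_system()]).  Residue
#' numbering is preserved from the file.
#'
#' @param path PDB file path.
#' @param model_index 1-based model to extract (files without MODEL
#'   records count as a single model).
#' @return a `molecular_system` with an attribute `n_models`.
#' @export
read_pdb <- function(path, model_index = 1L) {
  if (!file.exists(path)) stop("file not found: ", path)
  .check_pdb_records(path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE))
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_models <- nrow(xyz)
  if (model_index < 1 || model_index > n_models)
    stop("model_index ", model_index, " out of range (file has ",
         n_models, " model(s))")
  a <- pdb$atom
  elem <- a$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == ""))
    elem <- gsub("[0-9']", "", substr(trimws(a$elety), 1, 1))
  elem[is.na(elem) | elem == ""] <-
    gsub("[0-9']", "", substr(trimws(a$elety), 1, 1))[is.na(elem) |
                                                      elem == ""]
  chain <- a$chain
  chain[is.na(chain)] <- ""
  atoms <- data.frame(name = trimws(a$elety), element = trimws(elem),
                      resname = trimws(a$resid), resid = a$resno,
                      chain = chain, stringsAsFactors = FALSE)
  coords <- matrix(xyz[model_index, ], ncol = 3, byrow = TRUE)
  sys <- molecular_system(atoms, coords)
  attr(sys, "n_models") <- n_models
  sys
}

# fixed-width sanity scan so malformed coordinate records are reported
# with their line number before the parser sees them
.check_pdb_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grep("^(ATOM  |HETATM)", lines)
  for (i in rec) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop("malformed ATOM record (too short) at line ", i)
    coords <- c(substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))
    if (any(is.na(suppressWarnings(as.numeric(coords)))))
      stop("malformed ATOM record (non-numeric coordinates) at line ", i)
  }
  invisible(TRUE)
}

#' Write a (multi-model) PDB file
#'
#' Writes one or more coordinate sets for a system as a PDB v3.3 file with
#' MODEL/ENDMDL framing (single coordinate sets are written without model
#' records).  Coordinates survive a read/write round trip to the PDB
#' fixed-width precision of 1e-3 Angstrom.
#'
#' @param sys a `molecular_system`.
#' @param coords_list one coordinate matrix, or a list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(sys, coords_list = sys$xyz, path) {
  if (is.matrix(coords_list)) coords_list <- list(coords_list)
  n <- nrow(sys$atoms)
  for (m in seq_along(coords_list))
    if (nrow(coords_list[[m]]) != n || ncol(coords_list[[m]]) != 3)
      stop("coordinate set ", m, " does not match the atom count")
  a <- sys$atoms
  if (any(nchar(a$name) > 4)) stop("atom name longer than 4 characters")
  if (any(nchar(a$resname) > 3)) stop("residue name longer than 3 characters")
  if (any(nchar(substr(a$chain, 1, 2)) > 1)) stop("chain id longer than 1 character")
  if (any(a$resid > 9999)) stop("residue number exceeds PDB columns")
  fmt_name <- ifelse(nchar(a$name) < 4, sprintf(" %-3s", a$name),
                     sprintf("%-4s", a$name))
  multi <- length(coords_list) > 1
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(coords_list)) {
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    x <- coords_list[[m]]
    writeLines(sprintf(
      "ATOM  %5d %s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(n) %% 100000, fmt_name, a$resname,
      ifelse(a$chain == "", " ", a$chain), a$resid,
      x[, 1], x[, 2], x[, 3], 1, 0, a$element), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
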