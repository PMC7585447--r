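test_that("PDB write/read round trip preserves coordinates and models", {
  fx <- generate_fixture_peptide(4, seed = 2)
  sys <- fx$system
  pf <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(sys, list(sys$xyz, sys$xyz + 0.5), pf)

  r1 <- read_pdb(pf, 1)
  r2 <- read_pdb(pf, 2)
  expect_equal(attr(r1, "n_models"), 2)
  expect_lt(max(abs(r1$xyz - sys$xyz)), 1e-3)
  expect_lt(max(abs(r2$xyz - (sys$xyz + 0.5))), 1e-3)
  expect_identical(r1$atoms$name, sys$atoms$name)
  expect_identical(r1$atoms$resid, sys$atoms$resid)

  # parser model count equals a plain text scan of MODEL lines
  expect_equal(attr(r1, "n_models"),
               length(grep("^MODEL", readLines(pf))))

  # single coordinate set: no MODEL framing, still readable
  pf1 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(sys, sys$xyz, pf1)
  expect_equal(length(grep("^MODEL", readLines(pf1))), 0)
  expect_lt(max(abs(read_pdb(pf1)$xyz - sys$xyz)), 1e-3)
})

test_that("PDB reader validates input", {
  expect_error(read_pdb("no-such-file.pdb"), "not found")

  fx <- generate_fixture_peptide(2, seed = 1)
  pf <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(fx$system, fx$system$xyz, pf)
  expect_error(read_pdb(pf, 5), "out of range")

  lines <- readLines(pf)
  lines[3] <- paste0(substr(lines[3], 1, 30), "   xx.yyy",
                     substr(lines[3], 40, nchar(lines[3])))
  bad <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, bad)
  expect_error(read_pdb(bad), "line 3")
})

test_that("PDB writer enforces column bounds and shapes", {
  fx <- generate_fixture_peptide(2, seed = 1)
  sys <- fx$system
  pf <- withr::local_tempfile(fileext = ".pdb")
  expect_error(write_pdb(sys, sys$xyz[-1, ], pf), "atom count")
  sys_bad <- sys
  sys_bad$atoms$name[1] <- "HB123"
  expect_error(write_pdb(sys_bad, sys_bad$xyz, pf), "atom name")
  sys_bad2 <- sys
  sys_bad2$atoms$resname <- "ALAN"
  expect_error(write_pdb(sys_bad2, sys_bad2$xyz, pf), "residue name")
})

test_that("flat topology round trip reproduces the energy model", {
  fx <- generate_fixture_peptide(4, seed = 7)
  sys <- fx$system
  pf <- withr::local_tempfile(fileext = ".pdb")
  tf <- withr::local_tempfile(fileext = ".top")
  write_pdb(sys, sys$xyz, pf)
  write_topology(sys, tf)

  topo <- read_topology(tf)
  expect_lt(abs(sum(topo$charge)), 1e-6)  # neutral fixture
  full <- assemble_system(read_pdb(pf), topo)
  e0 <- total_energy(sys)
  e1 <- total_energy(full, sys$xyz)
  expect_lt(abs(e1[["E_total"]] - e0[["E_total"]]), 1e-4)
})

test_that("GROMACS-subset topology parses with unit conversion", {
  tf <- withr::local_tempfile(fileext = ".top")
  writeLines(c(
    "[ atomtypes ]",
    "CT 12.011 0.0 A 3.39967e-01 4.57730e-01",
    "HC 1.008 0.0 A 2.64953e-01 6.56888e-02",
    "[ atoms ]",
    "1 CT 1 ALA CA 1 -0.2 12.011",
    "2 HC 1 ALA HA 1  0.2 1.008",
    "3 CT 1 ALA CB 1  0.0 12.011",
    "[ bonds ]",
    "1 2 1 0.10900 284512.0",
    "1 3 1 0.15260 259408.0",
    "[ angles ]",
    "2 1 3 1 109.50 313.800",
    "[ dihedrals ]",
    "2 1 3 2 9 0.0 0.65084 3"), tf)
  g <- read_topology(tf)

  # hand-parsed reference of the same lines (nm -> A, kJ -> kcal,
  # GROMACS k/2 convention -> internal k)
  expect_equal(g$lj_sigma[1], 0.339967 * 10, tolerance = 1e-9)
  expect_equal(g$lj_eps[1], 0.457730 / 4.184, tolerance = 1e-9)
  expect_equal(g$bonds$kb[1], 284512 / 4.184 / 100 / 2, tolerance = 1e-9)
  expect_equal(g$bonds$r0[1], 1.09, tolerance = 1e-9)
  expect_equal(g$angles$kth[1], 313.8 / 4.184 / 2, tolerance = 1e-9)
  expect_equal(g$angles$th0[1], 109.5 * pi / 180, tolerance = 1e-9)
  expect_equal(g$dihedrals$per[1], 3)
  expect_equal(g$dihedrals$kphi[1], 0.65084 / 4.184, tolerance = 1e-9)
  expect_equal(g$dihedrals$improper[1], 0)
  expect_lt(abs(sum(g$charge)), 1e-6)
  # 1-2/1-3 exclusions derived from the bond graph
  expect_true(nrow(g$exclusions) >= 3)
})

test_that("topology rejects bad input", {
  tf <- withr::local_tempfile(fileext = ".top")
  writeLines(c("[ nonsense ]", "1 2 3"), tf)
  expect_error(read_topology(tf), "unknown directive")

  # a 1-4 pair that is also a 1-2 bond must be refused
  tf2 <- withr::local_tempfile(fileext = ".top")
  writeLines(c("#foldmc-topology",
               "[atoms]",
               "1 A1 C X 1 A 0 3 0.1 1.7",
               "2 A2 C X 1 A 0 3 0.1 1.7",
               "[bonds]", "1 2 300 1.5",
               "[pairs]", "1 2"), tf2)
  expect_error(read_topology(tf2), "both as 1-4")

  fx <- generate_fixture_peptide(3, seed = 1)
  tf3 <- withr::local_tempfile(fileext = ".top")
  write_topology(fx$system, tf3)
  struct <- generate_fixture_peptide(4, seed = 1)$system
  expect_error(assemble_system(struct, read_topology(tf3)),
               "atom count mismatch")
})

test_that("rotatable dihedral enumeration matches brute force", {
  fx <- generate_fixture_peptide(3, seed = 5)
  sys <- fx$system
  dih <- fx$dihedrals

  # independent enumeration: every bond whose removal disconnects the
  # graph into two parts of >= 2 atoms, except peptide C-N bonds
  n <- nrow(sys$atoms)
  reach <- function(start, skip) {
    seen <- logical(n); seen[start] <- TRUE; q <- start
    while (length(q)) {
      v <- q[1]; q <- q[-1]
      for (m in seq_len(nrow(sys$bonds))) {
        b <- c(sys$bonds$ai[m], sys$bonds$aj[m])
        if (all(sort(b) == sort(skip))) next
        if (b[1] == v && !seen[b[2]]) { seen[b[2]] <- TRUE; q <- c(q, b[2]) }
        if (b[2] == v && !seen[b[1]]) { seen[b[1]] <- TRUE; q <- c(q, b[1]) }
      }
    }
    which(seen)
  }
  expected <- list()
  for (m in seq_len(nrow(sys$bonds))) {
    b <- sys$bonds$ai[m]; cc <- sys$bonds$aj[m]
    side <- reach(b, c(b, cc))
    if (cc %in% side) next
    if (min(length(side), n - length(side)) < 2) next
    nm <- sys$atoms$name[c(b, cc)]
    ri <- sys$atoms$resid[c(b, cc)]
    if (setequal(nm, c("C", "N")) && ri[1] != ri[2]) next  # omega
    expected[[length(expected) + 1L]] <- sort(c(b, cc))
  }
  got <- lapply(dih, function(d) sort(d$bond))
  expect_setequal(vapply(got, paste, "", collapse = "-"),
                  vapply(expected, paste, "", collapse = "-"))

  # a residue's phi downstream set contains its psi downstream set
  for (r in 2:3) {
    phi <- Filter(function(d) d$class == "backbone-phi" &&
                    sys$atoms$resid[d$bond[1]] == r, dih)[[1]]
    psi <- Filter(function(d) d$class == "backbone-psi" &&
                    sys$atoms$resid[d$bond[1]] == r, dih)[[1]]
    expect_true(all(psi$downstream %in% phi$downstream))
  }
})

test_that("glycine has no chi torsions and proline has no phi", {
  # hand-built glycine-like residue pair: no CB on residue 2
  atoms <- data.frame(
    name = c("N", "H", "CA", "C", "O", "N", "H", "CA", "HA1", "HA2",
             "C", "O", "OXT"),
    element = c("N", "H", "C", "C", "O", "N", "H", "C", "H", "H",
                "C", "O", "O"),
    resname = c(rep("ALA", 5), rep("GLY", 8)),
    resid = c(rep(1L, 5), rep(2L, 8)), chain = "A")
  bonds <- data.frame(
    ai = c(1, 1, 3, 4, 4, 6, 6, 8, 8, 11, 11),
    aj = c(2, 3, 4, 5, 6, 7, 8, 9, 10, 12, 13),
    kb = 300, r0 = 1.5)
  bonds <- rbind(bonds, data.frame(ai = 8, aj = 11, kb = 300, r0 = 1.5))
  xyz <- cbind(seq_len(13) * 1.5, (seq_len(13) %% 2) * 0.5, 0)
  sys <- molecular_system(atoms, xyz, bonds = bonds)
  dih <- build_rotatable_dihedrals(sys)
  cls <- vapply(dih, `[[`, "", "class")
  expect_false(any(cls == "sidechain-chi"))

  # proline-like ring: N-CA-CB-CG-CD-N closed; phi absent, psi present
  atoms_p <- data.frame(
    name = c("C", "O", "N", "CA", "CB", "CG", "CD", "C", "O", "OXT"),
    element = c("C", "O", "N", "C", "C", "C", "C", "C", "O", "O"),
    resname = c("ALA", "ALA", rep("PRO", 8)),
    resid = c(1L, 1L, rep(2L, 8)), chain = "A")
  bonds_p <- data.frame(
    ai = c(1, 1, 3, 4, 5, 6, 7, 4, 8, 8),
    aj = c(2, 3, 4, 5, 6, 7, 3, 8, 9, 10),
    kb = 300, r0 = 1.5)
  th <- seq(0, 2 * pi, length.out = 11)[1:10]
  xyz_p <- cbind(3 * cos(th), 3 * sin(th), seq_len(10) * 0.1)
  sys_p <- molecular_system(atoms_p, xyz_p, bonds = bonds_p)
  dih_p <- build_rotatable_dihedrals(sys_p)
  cls_p <- vapply(dih_p, `[[`, "", "class")
  expect_false(any(cls_p == "backbone-phi"))
  expect_true(any(cls_p == "backbone-psi"))
  # ring bonds never appear as pivots
  for (d in dih_p)
    expect_false(all(d$bond %in% 3:7))
})

test_that("fixture generator is deterministic and clash-free", {
  a <- generate_fixture_peptide(5, seed = 11)
  b <- generate_fixture_peptide(5, seed = 11)
  expect_identical(a, b)
  expect_false(identical(a$system$xyz,
                         generate_fixture_peptide(5, seed = 12)$system$xyz))

  expect_equal(nrow(a$system$atoms), 10 * 5 + 2)
  d <- as.matrix(dist(a$system$xyz)); diag(d) <- Inf
  expect_gt(min(d), 0.5)
  expect_lt(abs(sum(a$system$charge)), 1e-9)
  expect_true(is.finite(total_energy(a$system)[["E_total"]]))
  expect_error(generate_fixture_peptide(0), "n_residues")
})

test_that("rotating a dihedral leaves all non-downstream geometry fixed", {
  fx <- generate_fixture_peptide(4, seed = 3)
  sys <- fx$system
  for (d in fx$dihedrals) {
    new <- rot_axis(sys$xyz, d$downstream - 1L,
                                 sys$xyz[d$bond[1], ], sys$xyz[d$bond[2], ],
                                 0.7)
    keep <- setdiff(seq_len(nrow(sys$xyz)), d$downstream)
    expect_identical(new[keep, ], sys$xyz[keep, ])
    dd <- as.matrix(dist(sys$xyz[keep, ])) - as.matrix(dist(new[keep, ]))
    expect_lt(max(abs(dd)), 1e-9)
  }
})

test_that("system invariants are enforced", {
  atoms <- data.frame(name = c("A", "B"), element = "C", resname = "X",
                      resid = 1:2, chain = "A")
  expect_error(molecular_system(atoms, matrix(0, 3, 3)),
               "does not match")
  expect_error(molecular_system(atoms, matrix(0, 2, 3),
                                bonds = data.frame(ai = 1, aj = 5,
                                                   kb = 1, r0 = 1)),
               "out of range")
  expect_error(molecular_system(atoms, matrix(0, 2, 3),
                                exclusions = cbind(1, 2),
                                pairs14 = cbind(2, 1)),
               "both as 1-4")
  expect_error(molecular_system(atoms, matrix(c(0, Inf, 0, 0, 0, 0), 2)),
               "non-finite")
})
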