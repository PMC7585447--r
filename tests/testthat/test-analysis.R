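# bead chains give exact control over which residue pairs are in contact
bead_ring <- function(n = 12, radius = 4) {
  th <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
  bead_system(cbind(radius * cos(th), radius * sin(th), 0))
}

test_that("native contact definition follows the distance and separation
           rules", {
  far <- bead_system(rbind(c(0, 0, 0), c(50, 0, 0), c(100, 0, 0),
                           c(150, 0, 0)))
  expect_equal(nrow(define_native_contacts(far, cutoff = 4.5)$pairs), 0)

  # adjacent residues within the cutoff are excluded by |i-j| >= 3
  near <- bead_system(rbind(c(0, 0, 0), c(2, 0, 0), c(4, 0, 0),
                            c(6, 0, 0)))
  ct <- define_native_contacts(near, cutoff = 4.5, min_separation = 3)
  expect_false(any(abs(ct$pairs$i - ct$pairs$j) < 3))

  # brute-force double loop oracle on a compact toy fold
  set.seed(9)
  sys <- bead_system(matrix(runif(30, 0, 8), ncol = 3))
  ct2 <- define_native_contacts(sys, cutoff = 5, min_separation = 3)
  expected <- list()
  for (i in 1:9) for (j in (i + 1):10) {
    if (j - i < 3) next
    d <- sqrt(sum((sys$xyz[i, ] - sys$xyz[j, ])^2))
    if (d < 5) expected[[length(expected) + 1L]] <- c(i, j, d)
  }
  exp_m <- do.call(rbind, expected)
  expect_equal(nrow(ct2$pairs), nrow(exp_m))
  expect_equal(ct2$pairs$i, exp_m[, 1])
  expect_equal(ct2$pairs$j, exp_m[, 2])
  expect_equal(ct2$pairs$native_d, exp_m[, 3], tolerance = 1e-9)

  expect_error(define_native_contacts(
    molecular_system(data.frame(name = "H1", element = "H",
                                resname = "X", resid = 1, chain = "A"),
                     matrix(0, 1, 3))), "heavy")
})

test_that("Q counts formed contacts and is exactly 1 at the reference", {
  ring <- bead_ring(12, 4)
  ct <- define_native_contacts(ring, cutoff = 6, min_separation = 3)
  expect_gt(nrow(ct$pairs), 0)
  expect_equal(compute_q(ring$xyz, ct), 1)

  blown <- ring$xyz * 100
  expect_equal(compute_q(blown, ct), 0)

  # break formed pairs one residue at a time: Q never increases
  q_prev <- 1
  xyz <- ring$xyz
  for (r in 1:12) {
    xyz[r, ] <- xyz[r, ] * 50
    q_now <- compute_q(xyz, ct)
    expect_lte(q_now, q_prev + 1e-12)
    q_prev <- q_now
  }
  expect_equal(q_prev, 0)

  empty <- define_native_contacts(bead_system(rbind(c(0, 0, 0),
                                                    c(90, 0, 0),
                                                    c(180, 0, 0),
                                                    c(270, 0, 0))))
  expect_error(compute_q(ring$xyz, empty), "empty contact set")
})

test_that("Q equals the exact formed fraction on a constructed case", {
  ring <- bead_ring(12, 4)
  ct <- define_native_contacts(ring, cutoff = 6, min_separation = 3)
  n <- nrow(ct$pairs)
  # remove residue 1 far away: exactly the contacts touching residue 1
  # break (lambda * native_d is always < the displacement)
  xyz <- ring$xyz
  xyz[1, ] <- c(500, 0, 0)
  touching <- sum(ct$pairs$i == 1 | ct$pairs$j == 1)
  expect_equal(compute_q(xyz, ct), (n - touching) / n)
})

test_that("per-residue nativeness matches hand counts and flags
           contact-free residues", {
  ring <- bead_ring(12, 4)
  ct <- define_native_contacts(ring, cutoff = 6, min_separation = 3)
  q0 <- per_residue_nativeness(ring$xyz, ct)
  expect_true(all(q0[!is.na(q0)] == 1))

  xyz <- ring$xyz
  xyz[1, ] <- c(500, 0, 0)
  qi <- per_residue_nativeness(xyz, ct)
  formed <- foldmc:::cpp_contacts_formed(xyz,
                                         foldmc:::contact_atom_pack(ct))
  for (r in 1:12) {
    sel <- ct$pairs$i == r | ct$pairs$j == r
    if (any(sel)) expect_equal(unname(qi[r]), mean(formed[sel]))
  }

  # a residue with no native contacts is NA
  line <- bead_system(rbind(c(0, 0, 0), c(2, 0, 0), c(4, 0, 0),
                            c(4, 2, 0), c(0, 2, 0), c(200, 0, 0)))
  ctl <- define_native_contacts(line, cutoff = 6, min_separation = 3)
  ql <- per_residue_nativeness(line$xyz, ctl)
  expect_true(is.na(ql["6"]))
})

test_that("PMF formula, masking and two-state free energy difference", {
  p <- pmf(runif(5000), 300, n_bins = 10)
  expect_true(all(abs(p$F[!is.na(p$F)]) < 0.1))  # near-flat

  # 73%/27% two-bin occupancy at 370 K
  q <- c(rep(0.25, 7300), rep(0.75, 2700))
  p2 <- pmf(q, 370, n_bins = 2)
  dF <- p2$F[2] - p2$F[1]
  expect_equal(dF, -1.9872041e-3 * 370 * log(2700 / 7300),
               tolerance = 1e-9)
  expect_equal(dF, 0.731, tolerance = 1e-3)

  # masked (empty) bins stay NA and are never minima
  q3 <- c(rep(0.1, 50), rep(0.5, 30), rep(0.9, 50))
  p3 <- pmf(q3, 300, n_bins = 10)
  expect_true(any(is.na(p3$F)))
  lb <- locate_minima_and_barriers(p3)
  expect_false(any(is.na(lb$minima$F)))
  expect_error(pmf(c(-0.1, 0.5), 300), "0, 1")
  expect_warning(pmf(rep(0.5, 100), 300, n_bins = 5), "single bin")
})

test_that("minima and barriers: constructed and randomized profiles", {
  lb <- locate_minima_and_barriers(c(0, 1, 0.5))
  expect_equal(lb$minima$bin, c(1, 3))
  expect_equal(lb$barriers$height_from_left, 1.0)
  expect_equal(lb$barriers$height_from_right, 0.5)

  flat <- locate_minima_and_barriers(c(1, 1, 1, 1))
  expect_equal(nrow(flat$barriers), 0)

  mono <- locate_minima_and_barriers(c(0, 1, 2, 3))
  expect_equal(nrow(mono$barriers), 0)

  set.seed(13)
  for (k in 1:5) {
    Fv <- runif(50)
    Fv[sample(50, 5)] <- NA
    lb <- locate_minima_and_barriers(Fv)
    expect_setequal(lb$minima$bin, bf_scan_minima(Fv))
  }

  # shift invariance: barrier heights ignore any constant offset
  Fv <- c(0, 1, 0.2, 1.5, 0.4)
  b0 <- locate_minima_and_barriers(Fv)$barriers
  b1 <- locate_minima_and_barriers(Fv + 7)$barriers
  expect_equal(b0$height_from_left, b1$height_from_left)
  expect_equal(b0$height_from_right, b1$height_from_right)

  expect_error(locate_minima_and_barriers(c(1, 2)), "3 unmasked")
})

test_that("folding temperature interpolates the dF sign change", {
  expect_equal(folding_temperature(c(0.5, -0.5), c(350, 360)), 355)
  expect_equal(folding_temperature(c(0.4, 0, -0.3), c(340, 352, 360)),
               352)
  # hand interpolation for a 3-point series
  dF <- c(0.8, 0.2, -0.4)
  Tt <- c(300, 320, 340)
  hand <- 320 + 0.2 / (0.2 + 0.4) * 20
  expect_equal(folding_temperature(dF, Tt), hand)
  expect_warning(out <- folding_temperature(c(1, 0.5, 0.2),
                                            c(300, 310, 320)),
                 "outside range")
  expect_true(is.na(out))
})

test_that("temperature calibration is a plain reversible shift", {
  expect_equal(calibrate_temperature(437, 83), 354)
  expect_equal(calibrate_temperature(400, 0), 400)
  expect_equal(calibrate_temperature(calibrate_temperature(437, 83), -83),
               437)
})

test_that("ensemble assignment uses left-closed intervals", {
  defn <- ensemble_definition(D = c(0, 0.3), I = c(0.35, 0.55),
                              TS = c(0.55, 0.65), N = c(0.7, 1))
  expect_equal(assign_ensembles(0.8, defn), "N")
  expect_equal(assign_ensembles(0.55, defn), "TS")   # boundary: left-closed
  expect_equal(assign_ensembles(0.33, defn), "unassigned")
  expect_equal(assign_ensembles(1.0, defn), "N")

  set.seed(3)
  q <- runif(500)
  lab <- assign_ensembles(q, defn)
  for (k in seq_along(q)) {
    hit <- "unassigned"
    for (nm in names(defn)) {
      v <- defn[[nm]]
      if (q[k] >= v[1] && (q[k] < v[2] || (v[2] == 1 && q[k] <= 1)))
        hit <- nm
    }
    if (hit != lab[k]) break
  }
  expect_equal(hit, lab[k])

  expect_error(ensemble_definition(D = c(0, 0.5), N = c(0.4, 1)),
               "overlap")
  expect_error(ensemble_definition(D = c(0.5, 0.4)), "invalid")
})

test_that("contact maps count ensemble frequencies exactly", {
  ring <- bead_ring(12, 4)
  ct <- define_native_contacts(ring, cutoff = 6, min_separation = 3)
  M <- contact_frequency_map(list(ring$xyz), ring, cutoff = 6)
  expect_true(isSymmetric(M))
  for (m in seq_len(nrow(ct$pairs)))
    expect_equal(M[ct$pairs$i[m], ct$pairs$j[m]], 1)
  expect_equal(sum(M > 0), 2 * nrow(ct$pairs))

  # 3-frame ensemble: frequencies are exact frame fractions
  x2 <- ring$xyz; x2[1, ] <- c(500, 0, 0)
  x3 <- ring$xyz * 100
  M3 <- contact_frequency_map(list(ring$xyz, x2, x3), ring, cutoff = 6)
  expect_true(all(M3 %in% c(0, 1 / 3, 2 / 3, 1)))
  pair1 <- ct$pairs[ct$pairs$i == 1, ][1, ]
  expect_equal(M3[pair1$i, pair1$j], 1 / 3)

  expect_equal(max(abs(difference_map(M3, M3))), 0)
  expect_error(contact_frequency_map(list(), ring), "empty")
  expect_error(difference_map(M3, M3[1:3, 1:3]), "dimensions")
})

test_that("phi-values: degenerate ensembles and hand Boltzmann weights", {
  nres <- 5
  set.seed(2)
  qN <- matrix(runif(3 * nres, 0.8, 1), 3, nres)
  qD <- matrix(runif(3 * nres, 0, 0.2), 3, nres)

  # TS identical to N -> phi = 1; TS identical to D -> phi = 0
  qmat <- rbind(qN, qD, qN)
  lab <- rep(c("N", "D", "TS"), each = 3)
  en <- rep(0, 9)
  ph1 <- phi_values(qmat, en, lab, 300)
  expect_equal(ph1$phi, rep(1, nres), tolerance = 1e-12)
  ph0 <- phi_values(rbind(qN, qD, qD), en, lab, 300)
  expect_equal(ph0$phi, rep(0, nres), tolerance = 1e-12)

  # two TS frames with energies differing by kB*T: weights 1/(1+e^-1),
  # e^-1/(1+e^-1)
  kBT <- 1.9872041e-3 * 300
  qTS <- rbind(rep(0.2, nres), rep(0.8, nres))
  qmat2 <- rbind(qN, qD, qTS)
  lab2 <- c(rep("N", 3), rep("D", 3), "TS", "TS")
  en2 <- c(rep(0, 6), 0, kBT)
  ph <- phi_values(qmat2, en2, lab2, 300)
  w1 <- 1 / (1 + exp(-1)); w2 <- exp(-1) / (1 + exp(-1))
  expect_equal(ph$q_TS, rep(w1 * 0.2 + w2 * 0.8, nres),
               tolerance = 1e-12)

  # uniform weights when all energies are identical
  expect_equal(phi_values(qmat2, rep(5, 8), lab2, 300)$q_TS,
               rep(0.5, nres), tolerance = 1e-12)

  # low N/D contrast is flagged
  phf <- phi_values(rbind(qN, qN, qN), en, lab, 300)
  expect_true(all(phf$flagged))
  expect_true(all(is.na(phf$phi)))
  expect_error(phi_values(qmat, en, rep("N", 9), 300), "empty ensemble")

  # bounds property: monotone ensembles give phi in [0, 1]
  set.seed(8)
  for (k in 1:10) {
    qd <- runif(nres, 0, 0.2); qn <- runif(nres, 0.8, 1)
    a <- runif(nres)
    qt <- qd + a * (qn - qd)
    ph <- phi_values(rbind(qn, qd, qt), rep(0, 3), c("N", "D", "TS"), 300)
    expect_true(all(ph$phi >= -1e-12 & ph$phi <= 1 + 1e-12))
  }
})

test_that("heat capacity recovers the fluctuation formula", {
  expect_equal(heat_capacity(list(rep(5, 100)), 300)$Cv, 0)

  set.seed(4)
  e <- rnorm(2e5, 100, 1)
  cv <- heat_capacity(list(e), 300)$Cv
  expect_equal(cv, 1 / (1.9872041e-3 * 300^2), tolerance = 0.02)
  # shifting all energies leaves Cv unchanged
  expect_equal(heat_capacity(list(e + 50), 300)$Cv, cv, tolerance = 1e-9)
  expect_error(heat_capacity(list(1), 300), "2 samples")
})

test_that("two-state Cv peak sits at its analytic location", {
  # two-state system: ground state energy 0, excited state dE with
  # degeneracy g.  The analytic heat capacity is
  # Cv(T) = dE^2 p (1 - p) / (kB T^2) with p = g e^{-dE/kBT} /
  # (1 + g e^{-dE/kBT}); its peak marks the folding-type crossover.
  dE <- 3; g <- 1000
  kB <- 1.9872041e-3
  temps <- seq(100, 500, by = 20)
  p_exc <- function(Tt) {
    w <- g * exp(-dE / (kB * Tt)); w / (1 + w)
  }
  cv_analytic <- dE^2 * p_exc(temps) * (1 - p_exc(temps)) /
    (kB * temps^2)
  T_peak <- temps[which.max(cv_analytic)]
  set.seed(6)
  es <- lapply(temps, function(Tt) dE * (runif(4e4) < p_exc(Tt)))
  cv <- heat_capacity(es, temps)
  expect_lte(abs(cv$temperature[which.max(cv$Cv)] - T_peak), 20)
})

test_that("Kabsch RMSD removes rigid transforms and matches references", {
  set.seed(1)
  A <- matrix(rnorm(30), 10, 3)
  expect_equal(kabsch_rmsd(A, A), 0)

  R <- rotation_matrix(c(1, 2, 3), 1.1)
  B <- A %*% t(R) + rep(c(4, -2, 7), each = 10)
  expect_lt(kabsch_rmsd(A, B), 1e-9)
  # symmetry
  Bn <- B + matrix(rnorm(30, 0, 0.3), 10, 3)
  expect_equal(kabsch_rmsd(A, Bn), kabsch_rmsd(Bn, A), tolerance = 1e-9)
  # cross-check against bio3d's fitted RMSD
  expect_equal(kabsch_rmsd(A, Bn),
               bio3d::rmsd(as.vector(t(A)), as.vector(t(Bn)), fit = TRUE),
               tolerance = 1e-3)

  # planar 4-point toy: brute-force scan over in-plane rotation angles
  P <- cbind(c(0, 2, 2, 0), c(0, 0, 1, 1), 0)
  th0 <- 0.6
  Q <- P %*% t(rotation_matrix(c(0, 0, 1), th0))
  Q[, 1] <- Q[, 1] + 0.1 * c(1, -1, 1, -1)   # in-plane distortion
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  grid <- seq(-pi, pi, by = 1e-4)
  best <- min(vapply(grid, function(th)
    sqrt(mean(rowSums((Qc %*% t(rotation_matrix(c(0, 0, 1), th)) -
                       Pc)^2))), numeric(1)))
  expect_equal(kabsch_rmsd(P, Q), best, tolerance = 1e-5)

  expect_error(kabsch_rmsd(A, A[1:5, ]), "counts differ")
  expect_error(kabsch_rmsd(A[1:2, ], A[1:2, ]), "3 atoms")
  # selection argument restricts both structures
  expect_equal(kabsch_rmsd(A, B, selection = 1:5), 0, tolerance = 1e-9)
})

test_that("hydrogen-bond distance is the minimum over the selections", {
  xyz <- rbind(c(0, 0, 0), c(2, 0, 0), c(3, 0, 0))
  expect_equal(hbond_distance(xyz, 1, c(2, 3)), 2.0)
  expect_error(hbond_distance(xyz, integer(0), 2), "empty")
})
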