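# Independent brute-force oracles, written separately from the package
# kernels: plain R double loops over the raw parameter tables.

rot_axis <- foldmc:::cpp_rotate_about_axis

KE <- 332.0636
KB <- 1.9872041e-3

# term-by-term bonded summation
bf_bonded <- function(sys, xyz = sys$xyz) {
  eb <- 0
  for (m in seq_len(nrow(sys$bonds))) {
    b <- sys$bonds[m, ]
    r <- sqrt(sum((xyz[b$ai, ] - xyz[b$aj, ])^2))
    eb <- eb + b$kb * (r - b$r0)^2
  }
  ea <- 0
  for (m in seq_len(nrow(sys$angles))) {
    a <- sys$angles[m, ]
    u <- xyz[a$ai, ] - xyz[a$aj, ]; v <- xyz[a$ak, ] - xyz[a$aj, ]
    th <- acos(pmin(1, pmax(-1, sum(u * v) / sqrt(sum(u^2) * sum(v^2)))))
    ea <- ea + a$kth * (th - a$th0)^2
  }
  et <- 0; ei <- 0
  for (m in seq_len(nrow(sys$dihedrals))) {
    d <- sys$dihedrals[m, ]
    phi <- bf_dihedral(xyz, d$ai, d$aj, d$ak, d$al)
    e <- d$kphi * (1 + cos(d$per * phi - d$phase))
    if (d$improper == 1) ei <- ei + e else et <- et + e
  }
  c(eb, ea, et, ei)
}

# dihedral via plane normals with signed angle (independent formulation)
bf_dihedral <- function(xyz, i, j, k, l) {
  b1 <- xyz[j, ] - xyz[i, ]; b2 <- xyz[k, ] - xyz[j, ]
  b3 <- xyz[l, ] - xyz[k, ]
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  ang <- acos(pmin(1, pmax(-1, sum(n1 * n2) /
                             sqrt(sum(n1^2) * sum(n2^2)))))
  if (sum(cr(n1, n2) * b2) < 0) ang <- -ang
  ang
}

# O(N^2) double loop over all pairs with exclusion/1-4 lookup
bf_nonbonded <- function(sys, xyz = sys$xyz, delta = 0.001) {
  n <- nrow(sys$atoms)
  exk <- paste(sys$exclusions[, 1], sys$exclusions[, 2])
  p14 <- paste(sys$pairs14[, 1], sys$pairs14[, 2])
  elj <- 0; ec <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    k <- paste(i, j)
    if (k %in% exk) next
    s14 <- k %in% p14
    r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2)) + delta
    ec <- ec + KE * sys$charge[i] * sys$charge[j] / r *
      (if (s14) 1 / 1.2 else 1)
    sig <- (sys$lj_sigma[i] + sys$lj_sigma[j]) / 2
    eps <- sqrt(sys$lj_eps[i] * sys$lj_eps[j])
    if (eps > 0)
      elj <- elj + 4 * eps * ((sig / r)^12 - (sig / r)^6) *
        (if (s14) 0.5 else 1)
  }
  c(elj, ec)
}

# OBC-II radii straight from the published formulas
bf_born <- function(sys, xyz = sys$xyz, p = solvent_params()) {
  n <- nrow(sys$atoms)
  rho <- sys$gb_radius - p$gb_offset
  scr <- p$gb_screen[sys$atoms$element]
  scr[is.na(scr)] <- p$gb_screen_default
  B <- numeric(n)
  for (i in seq_len(n)) {
    I <- 0
    for (j in seq_len(n)[-i]) {
      r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2)) + p$delta
      s <- scr[j] * rho[j]
      if (rho[i] >= r + s) next
      U <- r + s; L <- max(abs(r - s), rho[i])
      I <- I + 0.5 * (1 / L - 1 / U +
                      0.25 * (r - s^2 / r) * (1 / U^2 - 1 / L^2) +
                      log(L / U) / (2 * r))
      if (rho[i] < s - r) I <- I + 1 / rho[i] - 1 / L
    }
    psi <- I * rho[i]
    B[i] <- 1 / (1 / rho[i] -
                 tanh(p$gb_alpha * psi - p$gb_beta * psi^2 +
                      p$gb_gamma * psi^3) / sys$gb_radius[i])
  }
  B
}

bf_gb_energy <- function(charge, xyz, B, p = solvent_params()) {
  n <- length(charge)
  pref <- -0.5 * KE * (1 / p$eps_p - 1 / p$eps_w)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (charge[i] == 0 || charge[j] == 0) next
    if (i == j) { s <- s + charge[i]^2 / B[i]; next }
    r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2)) + p$delta
    f <- sqrt(r^2 + B[i] * B[j] * exp(-r^2 / (4 * B[i] * B[j])))
    s <- s + charge[i] * charge[j] / f
  }
  pref * s
}

# Shrake-Rupley with independent bookkeeping.  The quadrature definition
# (point set + molecule-frame orientation) is shared with the package;
# the occlusion logic is independent.
bf_frame <- function(xyz) {
  n <- nrow(xyz)
  e1 <- NULL
  for (t in seq_len(n)[-1]) {
    v <- xyz[t, ] - xyz[1, ]
    if (sqrt(sum(v^2)) > 1e-8) { e1 <- v / sqrt(sum(v^2)); jj <- t; break }
  }
  if (is.null(e1)) return(diag(3))
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  e3 <- NULL
  for (t in seq_len(n)[-seq_len(jj)]) {
    v <- cr(e1, xyz[t, ] - xyz[1, ])
    if (sqrt(sum(v^2)) > 1e-8) { e3 <- v / sqrt(sum(v^2)); break }
  }
  if (is.null(e3)) {
    ax <- which.min(abs(e1))
    u <- c(0, 0, 0); u[ax] <- 1
    v <- cr(e1, u); e3 <- v / sqrt(sum(v^2))
  }
  rbind(e1, cr(e3, e1), e3)
}

bf_sasa <- function(sys, xyz = sys$xyz, p = solvent_params(),
                    radii = NULL) {
  if (is.null(radii)) radii <- 2^(1 / 6) * sys$lj_sigma / 2
  pts <- sphere_points(p$sasa_points) %*% bf_frame(xyz)
  n <- nrow(xyz)
  area <- numeric(n)
  for (i in seq_len(n)) {
    if (radii[i] <= 0) next
    Ri <- radii[i] + p$probe
    surf <- sweep(pts * Ri, 2, xyz[i, ], "+")
    free <- rep(TRUE, nrow(surf))
    for (j in seq_len(n)[-i]) {
      if (radii[j] <= 0) next
      Rj <- radii[j] + p$probe
      d2 <- (surf[, 1] - xyz[j, 1])^2 + (surf[, 2] - xyz[j, 2])^2 +
        (surf[, 3] - xyz[j, 3])^2
      free <- free & d2 >= Rj^2
    }
    area[i] <- 4 * pi * Ri^2 * mean(free)
  }
  area
}

# monolithic from-scratch total energy
bf_total <- function(sys, xyz = sys$xyz, p = solvent_params()) {
  b <- bf_bonded(sys, xyz)
  nb <- bf_nonbonded(sys, xyz, p$delta)
  egb <- bf_gb_energy(sys$charge, xyz, bf_born(sys, xyz, p), p)
  enp <- p$gamma / 1000 * sum(bf_sasa(sys, xyz, p))
  sum(b) + sum(nb) + egb + enp
}

# single-heavy-atom "bead" chain: full control over residue geometry for
# contact/Q tests
bead_system <- function(pos) {
  n <- nrow(pos)
  atoms <- data.frame(name = "CA", element = "C", resname = "BEA",
                      resid = seq_len(n), chain = "A",
                      stringsAsFactors = FALSE)
  molecular_system(atoms, pos)
}

# independent minima/barrier scan
bf_scan_minima <- function(Fv) {
  u <- which(!is.na(Fv))
  f <- Fv[u]; k <- length(u)
  mins <- integer(0)
  for (t in seq_len(k)) {
    okl <- t == 1 || f[t] < f[t - 1]
    okr <- t == k || f[t] < f[t + 1]
    if (okl && okr) mins <- c(mins, u[t])
  }
  mins
}

rotation_matrix <- function(axis, theta) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * K %*% K
}
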