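# Folding-landscape analyses on the fraction of native contacts Q.

#' Define the native contact set
#'
#' A residue pair (i, j) is a native contact when the sequence separation
#' is at least `min_separation` and the minimum heavy-atom distance in the
#' reference structure is below `cutoff`.  The native minimum distance is
#' stored per pair; [compute_q()] counts a contact as formed when the
#' current minimum heavy-atom distance is below `lambda` times its native
#' value.  The reported Q at the folded minimum depends on these knobs, so
#' all of them are parameters.
#'
#' @param sys reference `molecular_system` (heavy atoms must be assigned
#'   to residues).
#' @param xyz reference coordinates (defaults to the system's).
#' @param cutoff heavy-atom distance cutoff in Angstrom.
#' @param min_separation minimum |i - j| in sequence.
#' @param lambda formation tolerance multiplier.
#' @param reference identifier recorded with the set.
#' @return a `native_contacts` object.
#' @export
define_native_contacts <- function(sys, xyz = sys$xyz, cutoff = 4.5,
                                   min_separation = 3, lambda = 1.2,
                                   reference = "reference") {
  heavy <- which(sys$atoms$element != "H")
  if (!length(heavy)) stop("no heavy atoms in reference structure")
  res <- sort(unique(sys$atoms$resid))
  by_res <- lapply(res, function(r)
    heavy[sys$atoms$resid[heavy] == r])
  nres <- length(res)
  pi_ <- integer(0); pj <- integer(0); nd <- numeric(0)
  ai <- list(); aj <- list()
  for (a in seq_len(nres - 1)) {
    for (b in seq_len(nres)[-seq_len(a)]) {
      if (abs(res[b] - res[a]) < min_separation) next
      if (!length(by_res[[a]]) || !length(by_res[[b]])) next
      d <- .min_block_dist(xyz, by_res[[a]], by_res[[b]])
      if (d < cutoff) {
        pi_ <- c(pi_, res[a]); pj <- c(pj, res[b]); nd <- c(nd, d)
        ai[[length(ai) + 1L]] <- by_res[[a]]
        aj[[length(aj) + 1L]] <- by_res[[b]]
      }
    }
  }
  structure(list(pairs = data.frame(i = pi_, j = pj, native_d = nd),
                 atoms_i = ai, atoms_j = aj, cutoff = cutoff,
                 min_separation = min_separation, lambda = lambda,
                 reference = reference, residues = res),
            class = "native_contacts")
}

.min_block_dist <- function(xyz, ia, ib) {
  A <- xyz[ia, , drop = FALSE]; B <- xyz[ib, , drop = FALSE]
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sqrt(max(0, min(d2)))
}

#' @export
print.native_contacts <- function(x, ...) {
  cat("Native contact set (", x$reference, "): ", nrow(x$pairs),
      " residue pairs\n", sep = "")
  cat("  cutoff ", x$cutoff, " A, |i-j| >= ", x$min_separation,
      ", lambda = ", x$lambda, "\n", sep = "")
  invisible(x)
}

# 0-based ragged pack for the compiled kernels
contact_atom_pack <- function(contacts) {
  list(atoms_i = lapply(contacts$atoms_i, function(v) as.integer(v - 1L)),
       atoms_j = lapply(contacts$atoms_j, function(v) as.integer(v - 1L)),
       threshold = contacts$lambda * contacts$pairs$native_d)
}

#' Fraction of native contacts
#'
#' @param xyz coordinates covering all contact atoms.
#' @param contacts a [define_native_contacts()] set (nonempty).
#' @return Q in `[0, 1]`; the reference coordinates give exactly 1.
#' @export
compute_q <- function(xyz, contacts) {
  if (nrow(contacts$pairs) == 0)
    stop("Q is undefined for an empty contact set")
  mean(cpp_contacts_formed(as.matrix(xyz), contact_atom_pack(contacts)))
}

#' Per-residue nativeness
#'
#' Fraction of each residue's native contacts currently formed.  Residues
#' with no native contacts are undefined (NA), mirroring the blank rows in
#' per-residue stability maps.
#'
#' @inheritParams compute_q
#' @return named numeric vector over residues (NA where undefined).
#' @export
per_residue_nativeness <- function(xyz, contacts) {
  formed <- cpp_contacts_formed(as.matrix(xyz), contact_atom_pack(contacts))
  res <- contacts$residues
  out <- setNames(rep(NA_real_, length(res)), res)
  for (k in seq_along(res)) {
    r <- res[k]
    sel <- contacts$pairs$i == r | contacts$pairs$j == r
    if (any(sel)) out[k] <- mean(formed[sel])
  }
  out
}

#' Potential of mean force over Q
#'
#' `F(Q_b) = -k_B T log P(Q_b)`, shifted so the minimum is zero; empty
#' bins are masked (NA), never treated as zero.
#'
#' @param q_samples post-equilibration Q values in `[0, 1]`.
#' @param temperature temperature in K.
#' @param n_bins number of bins over `[0, 1]`.
#' @param params a [solvent_params()] (supplies `k_B`).
#' @return a `fold_pmf`: data.frame with `bin_mid`, `count`, `P`, `F`
#'   plus the temperature as an attribute.
#' @export
pmf <- function(q_samples, temperature, n_bins = 50,
                params = solvent_params()) {
  if (any(q_samples < 0 | q_samples > 1, na.rm = TRUE))
    stop("Q samples must lie in [0, 1]")
  q_samples <- q_samples[!is.na(q_samples)]
  breaks <- seq(0, 1, length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(q_samples, breaks, rightmost.closed = TRUE),
                   1L), n_bins)
  count <- tabulate(bin, nbins = n_bins)
  if (sum(count > 0) == 1)
    warning("all Q samples fall in a single bin; PMF is degenerate")
  P <- count / sum(count)
  F <- ifelse(count > 0, -params$k_B * temperature * log(P), NA_real_)
  F <- F - min(F, na.rm = TRUE)
  out <- data.frame(bin_mid = (breaks[-1] + breaks[-(n_bins + 1)]) / 2,
                    count = count, P = P, F = F)
  structure(out, class = c("fold_pmf", "data.frame"),
            temperature = temperature)
}

#' @export
plot.fold_pmf <- function(x, ...) {
  plot(x$bin_mid, x$F, type = "b", xlab = "Q",
       ylab = "F(Q) (kcal/mol)", ...)
  invisible(x)
}

#' Locate free-energy minima and barriers
#'
#' Local minima are unmasked bins strictly lower than both unmasked
#' neighbors (profile ends compare against their single neighbor).  The
#' barrier between two adjacent minima is the maximum of the profile
#' between them, reported as a height from each minimum separately
#' (the dG_{N,I} / dG_{I,N} convention).
#'
#' @param profile a [pmf()] object, or a numeric F(Q) vector (NA = masked).
#' @param q optional bin positions for a numeric profile.
#' @return list with `minima` (data.frame: bin, Q, F) and `barriers`
#'   (data.frame: from/to minima bins, peak bin, height from each side);
#'   both empty for monotone or flat profiles.
#' @export
locate_minima_and_barriers <- function(profile, q = NULL) {
  if (inherits(profile, "fold_pmf")) {
    Fv <- profile$F; q <- profile$bin_mid
  } else {
    Fv <- as.numeric(profile)
    if (is.null(q)) q <- seq_along(Fv)
  }
  u <- which(!is.na(Fv))
  if (length(u) < 3)
    stop("need at least 3 unmasked bins")
  f <- Fv[u]
  k <- length(u)
  is_min <- vapply(seq_len(k), function(t) {
    left <- if (t > 1) f[t] < f[t - 1] else TRUE
    right <- if (t < k) f[t] < f[t + 1] else TRUE
    left && right && (t > 1 || k > 1)
  }, logical(1))
  mins <- u[is_min]
  minima <- data.frame(bin = mins, Q = q[mins], F = Fv[mins])
  barriers <- NULL
  if (length(mins) >= 2) {
    rows <- lapply(seq_len(length(mins) - 1), function(t) {
      lo <- which(u == mins[t]); hi <- which(u == mins[t + 1])
      seg <- u[lo:hi]
      pk <- seg[which.max(Fv[seg])]
      data.frame(from_bin = mins[t], to_bin = mins[t + 1], peak_bin = pk,
                 peak_Q = q[pk],
                 height_from_left = Fv[pk] - Fv[mins[t]],
                 height_from_right = Fv[pk] - Fv[mins[t + 1]])
    })
    barriers <- do.call(rbind, rows)
  } else {
    barriers <- data.frame(from_bin = integer(0), to_bin = integer(0),
                           peak_bin = integer(0), peak_Q = numeric(0),
                           height_from_left = numeric(0),
                           height_from_right = numeric(0))
  }
  list(minima = minima, barriers = barriers)
}

#' Folding temperature by interpolation
#'
#' The temperature where the folded (highest-Q) and unfolded (lowest-Q)
#' minima are equally probable, i.e. where
#' `dF(T) = F(folded) - F(unfolded)` crosses zero, located by linear
#' interpolation in T.
#'
#' @param profiles list of [pmf()] objects (one per temperature), or a
#'   numeric vector of dF values directly.
#' @param temperatures temperatures in K matching `profiles`.
#' @return folding temperature in K, or NA (with a warning) when dF does
#'   not change sign over the series.
#' @export
folding_temperature <- function(profiles, temperatures) {
  if (is.numeric(profiles)) {
    dF <- profiles
  } else {
    dF <- vapply(profiles, function(p) {
      mm <- locate_minima_and_barriers(p)$minima
      if (nrow(mm) < 2)
        return(NA_real_)
      mm <- mm[order(mm$Q), ]
      mm$F[nrow(mm)] - mm$F[1]
    }, numeric(1))
  }
  ok <- which(!is.na(dF))
  if (length(ok) < 1) stop("no profile with two identifiable minima")
  dF <- dF[ok]; temperatures <- temperatures[ok]
  z <- which(dF == 0)
  if (length(z)) return(temperatures[z[1]])
  s <- which(diff(sign(dF)) != 0)
  if (!length(s)) {
    warning("dF does not change sign: folding temperature outside range")
    return(NA_real_)
  }
  i <- s[1]
  temperatures[i] + (0 - dF[i]) * (temperatures[i + 1] - temperatures[i]) /
    (dF[i + 1] - dF[i])
}

#' Temperature calibration shift
#'
#' Applies a constant calibration shift to simulation temperatures for
#' reporting: `T_reported = T_sim - shift`.  Raw temperatures should be
#' preserved alongside.
#'
#' @param T_sim simulation temperature(s) in K.
#' @param shift calibration shift in K.
#' @return shifted temperature(s).
#' @export
calibrate_temperature <- function(T_sim, shift) T_sim - shift

#' Ensemble definition over Q intervals
#'
#' @param ... named intervals, e.g. `D = c(0, 0.3)`, `TS = c(0.55, 0.65)`,
#'   `N = c(0.7, 1)`; intervals must lie in `[0, 1]`, be nonempty and not
#'   overlap.
#' @return an `ensemble_definition`.
#' @export
ensemble_definition <- function(...) {
  iv <- list(...)
  if (!length(iv) || is.null(names(iv)) || any(names(iv) == ""))
    stop("intervals must be named")
  for (nm in names(iv)) {
    v <- iv[[nm]]
    if (length(v) != 2 || v[1] >= v[2] || v[1] < 0 || v[2] > 1)
      stop("invalid interval for ", nm)
  }
  lo <- vapply(iv, `[`, 1, 1)
  o <- order(lo)
  hi <- vapply(iv, `[`, 1, 2)
  if (any(hi[o][-length(iv)] > lo[o][-1]))
    stop("overlapping ensemble intervals")
  structure(iv, class = "ensemble_definition")
}

#' Assign frames to ensembles
#'
#' Each frame is labeled by the interval containing its Q.  Intervals are
#' closed on the left and open on the right, except that an interval
#' ending exactly at 1 also contains 1.
#'
#' @param q_values per-frame Q values.
#' @param definition an [ensemble_definition()].
#' @return character vector of labels (`"unassigned"` where no interval
#'   matches).
#' @export
assign_ensembles <- function(q_values, definition) {
  if (!inherits(definition, "ensemble_definition"))
    definition <- do.call(ensemble_definition, as.list(definition))
  out <- rep("unassigned", length(q_values))
  for (nm in names(definition)) {
    v <- definition[[nm]]
    inside <- q_values >= v[1] &
      (q_values < v[2] | (v[2] == 1 & q_values <= 1))
    out[inside] <- nm
  }
  out
}

#' Ensemble contact frequency map
#'
#' Entry (i, j) is the fraction of the supplied frames in which residues i
#' and j are in contact, using the same geometric rule as
#' [define_native_contacts()] (minimum heavy-atom distance below the
#' cutoff) applied frame by frame.  Symmetric with values in `[0, 1]`.
#'
#' @param frames list of coordinate matrices (one per frame).
#' @param sys the `molecular_system` (for residue/heavy-atom assignment).
#' @param cutoff,min_separation contact rule parameters.
#' @return residue x residue frequency matrix (named by residue number).
#' @export
contact_frequency_map <- function(frames, sys, cutoff = 4.5,
                                  min_separation = 3) {
  if (!length(frames)) stop("empty ensemble")
  heavy <- which(sys$atoms$element != "H")
  res <- sort(unique(sys$atoms$resid))
  by_res <- lapply(res, function(r) heavy[sys$atoms$resid[heavy] == r])
  nres <- length(res)
  M <- matrix(0, nres, nres, dimnames = list(res, res))
  for (xyz in frames) {
    for (a in seq_len(nres - 1)) {
      for (b in seq_len(nres)[-seq_len(a)]) {
        if (abs(res[b] - res[a]) < min_separation) next
        if (.min_block_dist(xyz, by_res[[a]], by_res[[b]]) < cutoff) {
          M[a, b] <- M[a, b] + 1
          M[b, a] <- M[b, a] + 1
        }
      }
    }
  }
  M / length(frames)
}

#' Contact difference map
#'
#' @param mapA,mapB frequency maps of equal dimension.
#' @return the signed elementwise difference `A - B`.
#' @export
difference_map <- function(mapA, mapB) {
  if (!all(dim(mapA) == dim(mapB))) stop("map dimensions differ")
  mapA - mapB
}

#' Per-residue phi-values
#'
#' Boltzmann-weighted per-residue nativeness within the denatured (D),
#' transition-state (TS) and native (N) ensembles, combined as
#' `phi_i = (<q_i>_TS - <q_i>_D) / (<q_i>_N - <q_i>_D)`.  Frame weights
#' within an ensemble are `w ~ exp(-E / k_B T)`, normalized per ensemble.
#' The unnormalized variant `<q_i>_TS` is returned alongside.  Residues
#' whose q is undefined, or whose N/D contrast is below `floor`, are
#' flagged; out-of-range values are reported, never clipped.
#'
#' @param q_res matrix of per-residue nativeness, frames x residues
#'   (rows from [per_residue_nativeness()]).
#' @param energies per-frame energies (kcal/mol).
#' @param labels per-frame ensemble labels containing `"D"`, `"TS"`,
#'   `"N"` (others ignored).
#' @param temperature temperature in K for the Boltzmann weights.
#' @param params a [solvent_params()].
#' @param floor minimum |<q>_N - <q>_D| for a defined phi.
#' @return data.frame with per-residue `q_D`, `q_TS`, `q_N`, `phi`,
#'   `phi_unnormalized` and a `flagged` indicator.
#' @export
phi_values <- function(q_res, energies, labels, temperature,
                       params = solvent_params(), floor = 0.1) {
  q_res <- as.matrix(q_res)
  stopifnot(nrow(q_res) == length(energies),
            nrow(q_res) == length(labels))
  ens_avg <- function(ens) {
    sel <- which(labels == ens)
    if (!length(sel)) stop("empty ensemble: ", ens)
    e <- energies[sel]
    w <- exp(-(e - min(e)) / (params$k_B * temperature))
    w <- w / sum(w)
    colSums(q_res[sel, , drop = FALSE] * w)
  }
  qD <- ens_avg("D"); qTS <- ens_avg("TS"); qN <- ens_avg("N")
  denom <- qN - qD
  phi <- (qTS - qD) / denom
  flagged <- is.na(phi) | abs(denom) < floor
  phi[abs(denom) < floor] <- NA_real_
  data.frame(residue = colnames(q_res) %||% seq_len(ncol(q_res)),
             q_D = qD, q_TS = qTS, q_N = qN, phi = phi,
             phi_unnormalized = qTS, flagged = flagged,
             row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Heat capacity from energy fluctuations
#'
#' `Cv(T) = (<E^2> - <E>^2) / (k_B T^2)` per temperature (population
#' variance of post-equilibration energies).
#'
#' @param energy_samples list of energy vectors, one per temperature.
#' @param temperatures temperatures in K.
#' @param params a [solvent_params()].
#' @return data.frame with `temperature` and `Cv` (kcal/mol/K).
#' @export
heat_capacity <- function(energy_samples, temperatures,
                          params = solvent_params()) {
  if (!is.list(energy_samples)) energy_samples <- list(energy_samples)
  stopifnot(length(energy_samples) == length(temperatures))
  cv <- vapply(seq_along(temperatures), function(i) {
    e <- energy_samples[[i]]
    if (length(e) < 2) stop("need at least 2 samples per temperature")
    (mean(e^2) - mean(e)^2) / (params$k_B * temperatures[i]^2)
  }, numeric(1))
  data.frame(temperature = temperatures, Cv = cv)
}

#' Kabsch RMSD
#'
#' Root-mean-square deviation after optimal least-squares superposition
#' (proper rotations only), symmetric in its arguments.
#'
#' @param A,B coordinate matrices with matching atom order.
#' @param selection optional atom indices used for both structures.
#' @return RMSD in Angstrom.
#' @export
kabsch_rmsd <- function(A, B, selection = NULL) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (!is.null(selection)) {
    A <- A[selection, , drop = FALSE]
    B <- B[selection, , drop = FALSE]
  }
  if (nrow(A) != nrow(B)) stop("atom counts differ")
  if (nrow(A) < 3) stop("need at least 3 atoms")
  Ac <- sweep(A, 2, colMeans(A))
  Bc <- sweep(B, 2, colMeans(B))
  s <- svd(t(Bc) %*% Ac)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fit <- Bc %*% t(R)
  sqrt(mean(rowSums((fit - Ac)^2)))
}

#' Minimum hydrogen-acceptor distance
#'
#' @param xyz coordinates.
#' @param donor_hydrogens indices of donor hydrogen atoms (nonempty).
#' @param acceptors indices of acceptor atoms (nonempty).
#' @return the minimum H...acceptor Euclidean distance in Angstrom.
#' @export
hbond_distance <- function(xyz, donor_hydrogens, acceptors) {
  if (!length(donor_hydrogens) || !length(acceptors))
    stop("empty atom selection")
  .min_block_dist(as.matrix(xyz), donor_hydrogens, acceptors)
}
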