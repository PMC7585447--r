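#' Monte Carlo run configuration
#'
#' @param temperature simulation temperature in K, `> 0`.
#' @param n_steps number of MC steps.
#' @param seed RNG seed; together with the config and inputs it determines
#'   the trajectory bit for bit.
#' @param move_weights weights for `c(dihedral, concerted, rigid)` moves;
#'   the defaults keep dihedral and concerted moves equally probable with a
#'   small rigid-rotation share.
#' @param width_deg Gaussian width (SD) of dihedral move angles, degrees.
#' @param width_concerted_deg Gaussian width of concerted move angles;
#'   defaults to `width_deg`.
#' @param concerted_window concerted-move window length in residues.
#' @param rigid_max_deg maximum rigid-rotation angle, degrees.
#' @param stride record every `stride`-th step.
#' @param equil_frac fraction of initial records flagged as equilibration
#'   and excluded from ensemble statistics.
#' @param restraint optional Q-restraint: `list(Q0 = , k = )` giving a
#'   one-sided harmonic wall `k * (Q0 - Q)^2` for `Q < Q0`.
#' @param contacts optional [define_native_contacts()] set; required for
#'   the restraint and enables Q recording.
#' @param energy_terms energy groups to evaluate each step.
#' @param record_coords record coordinates at every stored frame.
#' @param params a [solvent_params()].
#' @return an `mc_config` list.
#' @export
mc_config <- function(temperature = 300, n_steps = 10000L, seed = 1L,
                      move_weights = c(0.45, 0.45, 0.10),
                      width_deg = 20, width_concerted_deg = width_deg,
                      concerted_window = 4L, rigid_max_deg = 5,
                      stride = max(1L, n_steps %/% 1000L),
                      equil_frac = 0.10, restraint = NULL, contacts = NULL,
                      energy_terms = c("bonded", "nonbonded", "gb", "sasa"),
                      record_coords = FALSE, params = solvent_params()) {
  if (temperature <= 0) stop("temperature must be > 0")
  if (equil_frac < 0 || equil_frac >= 1) stop("equil_frac must be in [0,1)")
  if (stride < 1) stop("stride must be >= 1")
  if (length(move_weights) != 3 || any(move_weights < 0) ||
      sum(move_weights) <= 0) stop("invalid move weights")
  if (!is.null(restraint)) {
    stopifnot(is.list(restraint), !is.null(restraint$Q0),
              !is.null(restraint$k))
    if (is.null(contacts)) stop("restraint requires a contact set")
  }
  structure(list(temperature = temperature, n_steps = as.integer(n_steps),
                 seed = as.integer(seed),
                 move_weights = move_weights / sum(move_weights),
                 width_deg = width_deg,
                 width_concerted_deg = width_concerted_deg,
                 concerted_window = as.integer(concerted_window),
                 rigid_max_deg = rigid_max_deg, stride = as.integer(stride),
                 equil_frac = equil_frac, restraint = restraint,
                 contacts = contacts, energy_terms = energy_terms,
                 record_coords = record_coords, params = params),
            class = "mc_config")
}

#' Metropolis acceptance criterion
#'
#' Accepts with probability `min(1, exp(-delta_E / (k_B T)))`; moves that
#' lower the energy are always accepted.  One uniform variate is consumed
#' per call regardless of the outcome, matching the compiled MC loop's
#' draw protocol.
#'
#' @param delta_E energy change in kcal/mol.
#' @param temperature temperature in K, `> 0`.
#' @param params a [solvent_params()] (supplies `k_B`).
#' @return logical: accept the move?
#' @export
metropolis_accept <- function(delta_E, temperature,
                              params = solvent_params()) {
  if (temperature <= 0) stop("temperature must be > 0")
  u <- runif(1)
  delta_E <= 0 || u < exp(-delta_E / (params$k_B * temperature))
}

#' Q-restraint wall energy
#'
#' One-sided harmonic wall that pushes the fraction of native contacts
#' back above `Q0`: zero for `Q >= Q0`, `k_Q (Q0 - Q)^2` below, continuous
#' with continuous first derivative at the wall.
#'
#' @param Q fraction of native contacts, in `[0, 1]`.
#' @param Q0 wall position.
#' @param k_Q force constant, kcal/mol per unit Q^2.
#' @return energy in kcal/mol (vectorized in `Q`).
#' @export
q_restraint_energy <- function(Q, Q0, k_Q = 100) {
  ifelse(Q < Q0, k_Q * (Q0 - Q)^2, 0)
}

#' Initialize a Monte Carlo state
#'
#' @param sys a `molecular_system`.
#' @param config an [mc_config()].
#' @param dihedrals optional precomputed rotatable set.
#' @return an `mc_state` list holding coordinates, the current energy
#'   breakdown, Q, move bookkeeping and cached tables; feed it to
#'   [mc_step()].
#' @export
init_mc_state <- function(sys, config, dihedrals = NULL) {
  if (is.null(dihedrals)) dihedrals <- build_rotatable_dihedrals(sys)
  wins <- if (config$move_weights[2] > 0)
    concerted_windows(sys, config$concerted_window) else list()
  if (config$move_weights[1] > 0 && length(dihedrals) == 0)
    stop("dihedral moves requested but no rotatable dihedrals")
  if (config$move_weights[2] > 0 && length(wins) == 0)
    stop("concerted moves requested but no usable windows")
  pack <- pack_energy(sys, config$params, config$energy_terms)
  e <- total_energy(sys, sys$xyz, config$params,
                    restraint = config$restraint,
                    contacts = config$contacts,
                    terms = config$energy_terms, pack = pack)
  q <- if (!is.null(config$contacts)) compute_q(sys$xyz, config$contacts)
       else NA_real_
  list(xyz = sys$xyz, energy = e, Q = q,
       proposed = c(dihedral = 0L, concerted = 0L, rigid = 0L),
       accepted = c(dihedral = 0L, concerted = 0L, rigid = 0L),
       dihedrals = dihedrals, windows = wins, pack = pack)
}

#' Advance one Monte Carlo step
#'
#' Propose with [select_move()], score with [total_energy()] (plus the Q
#' restraint when enabled), accept with [metropolis_accept()].  On
#' rejection coordinates and energy are restored exactly (the proposal is
#' discarded, nothing is recomputed).  This R-level path consumes the same
#' random variates as the compiled loop in [run_simulation()], so both
#' produce identical chains from the same seed.
#'
#' @param state an [init_mc_state()] object.
#' @param sys the `molecular_system`.
#' @param config the [mc_config()].
#' @return the updated state.
#' @export
mc_step <- function(state, sys, config) {
  kind <- select_move(config$move_weights)
  prop <- switch(kind,
    dihedral = dihedral_move(sys, state$dihedrals, state$xyz,
                             config$width_deg),
    concerted = {
      nw <- length(state$windows)
      m <- min(floor(runif(1) * nw) + 1, nw)
      ang <- rnorm(1) * (config$width_concerted_deg * pi / 180)
      w <- state$windows[[m]]
      structure(list(xyz = cpp_rotate_about_axis(state$xyz, w$moved - 1L,
                                                 state$xyz[w$a1, ],
                                                 state$xyz[w$a2, ], ang),
                     kind = "concerted", changed = w$moved,
                     meta = list(index = m, angle_deg = ang * 180 / pi,
                                 anchors = c(w$a1, w$a2),
                                 inverse_angle_deg = -ang * 180 / pi)),
                class = "move_proposal")
    },
    rigid = rigid_rotation_move(state$xyz, config$rigid_max_deg))
  state$proposed[kind] <- state$proposed[kind] + 1L
  enew <- total_energy(sys, prop$xyz, config$params,
                       restraint = config$restraint,
                       contacts = config$contacts,
                       terms = config$energy_terms, pack = state$pack)
  dE <- enew[["E_total"]] - state$energy[["E_total"]]
  if (metropolis_accept(dE, config$temperature, config$params)) {
    state$accepted[kind] <- state$accepted[kind] + 1L
    state$xyz <- prop$xyz
    state$energy <- enew
    if (!is.null(config$contacts))
      state$Q <- compute_q(state$xyz, config$contacts)
  }
  state
}

#' Run a Metropolis Monte Carlo simulation
#'
#' Executes `config$n_steps` steps from the system's coordinates with the
#' compiled inner loop (full energy recomputation at every step), records
#' every `config$stride` steps, flags the first `config$equil_frac` of the
#' records as equilibration, and tallies per-kind proposal/acceptance
#' counts.  Fully reproducible from `(seed, config, inputs)`.
#'
#' @inheritParams init_mc_state
#' @return an `mc_trajectory`: list with `records` (data.frame: step,
#'   per-term energies, `E_total`, `Q`, `equil` flag), `coords` (list of
#'   recorded coordinate matrices, when requested), `proposed`/`accepted`
#'   counters, `acceptance_ratio`, `final_xyz` and the `config` echo.
#' @export
run_simulation <- function(sys, config, dihedrals = NULL) {
  if (is.null(dihedrals)) dihedrals <- build_rotatable_dihedrals(sys)
  wins <- if (config$move_weights[2] > 0)
    concerted_windows(sys, config$concerted_window) else list()
  if (config$move_weights[1] > 0 && length(dihedrals) == 0)
    stop("dihedral moves requested but no rotatable dihedrals")
  if (config$move_weights[2] > 0 && length(wins) == 0)
    stop("concerted moves requested but no usable windows")
  pack <- pack_energy(sys, config$params, config$energy_terms)
  moves <- list(
    weights = config$move_weights,
    dih_b = vapply(dihedrals, function(d) d$bond[1], 1) - 1L,
    dih_c = vapply(dihedrals, function(d) d$bond[2], 1) - 1L,
    dih_down = lapply(dihedrals, function(d) as.integer(d$downstream - 1L)),
    width_dih = config$width_deg * pi / 180,
    width_conc = config$width_concerted_deg * pi / 180,
    win_a1 = vapply(wins, function(w) w$a1, 1) - 1L,
    win_a2 = vapply(wins, function(w) w$a2, 1) - 1L,
    win_moved = lapply(wins, function(w) as.integer(w$moved - 1L)),
    rigid_max = config$rigid_max_deg * pi / 180)
  have_contacts <- !is.null(config$contacts)
  cfg <- list(n_steps = config$n_steps, stride = config$stride,
              record_coords = config$record_coords,
              temperature = config$temperature, kB = config$params$k_B,
              restraint_on = !is.null(config$restraint),
              Q0 = if (is.null(config$restraint)) 0 else config$restraint$Q0,
              kQ = if (is.null(config$restraint)) 0 else config$restraint$k,
              have_contacts = have_contacts,
              contacts = if (have_contacts)
                contact_atom_pack(config$contacts) else list())
  set.seed(config$seed)
  res <- cpp_run_mc(sys$xyz, pack, moves, cfg)
  rec <- as.data.frame(res$records)
  names(rec) <- c("step", "E_bond", "E_angle", "E_torsion", "E_improper",
                  "E_LJ", "E_Coulomb", "E_GB", "E_nonpolar", "E_restraint",
                  "E_total", "Q")
  n_rec <- nrow(rec)
  rec$equil <- seq_len(n_rec) <= floor(config$equil_frac * n_rec)
  coords <- NULL
  if (config$record_coords && n_rec > 0) {
    n <- nrow(sys$xyz)
    coords <- lapply(seq_len(n_rec), function(i)
      matrix(res$coords[i, ], n, 3))
  }
  proposed <- setNames(res$proposed, c("dihedral", "concerted", "rigid"))
  accepted <- setNames(res$accepted, c("dihedral", "concerted", "rigid"))
  structure(list(records = rec, coords = coords, proposed = proposed,
                 accepted = accepted,
                 acceptance_ratio = sum(accepted) / max(1, sum(proposed)),
                 final_xyz = res$final_xyz, config = config),
            class = "mc_trajectory")
}

#' Run a series of simulations over temperatures
#'
#' Independent seeded runs (seed `config$seed + index - 1`) at each
#' temperature, with per-temperature summaries for downstream heat
#' capacity and PMF analysis.
#'
#' @param sys a `molecular_system`.
#' @param temperatures vector of temperatures in K.
#' @param config base [mc_config()]; its temperature/seed are overridden
#'   per run.
#' @return a `temperature_series` list: `trajectories`, `temperatures`,
#'   and a `summary` data.frame (temperature, mean and variance of
#'   post-equilibration `E_total`, mean Q).
#' @export
temperature_series <- function(sys, temperatures, config) {
  if (length(temperatures) < 1) stop("empty temperature list")
  trajs <- lapply(seq_along(temperatures), function(i) {
    cfg <- config
    cfg$temperature <- temperatures[i]
    cfg$seed <- config$seed + i - 1L
    run_simulation(sys, cfg)
  })
  sm <- do.call(rbind, lapply(seq_along(trajs), function(i) {
    r <- trajs[[i]]$records
    keep <- r[!r$equil, , drop = FALSE]
    data.frame(temperature = temperatures[i],
               mean_E = mean(keep$E_total),
               var_E = mean(keep$E_total^2) - mean(keep$E_total)^2,
               mean_Q = mean(keep$Q))
  }))
  structure(list(trajectories = trajs, temperatures = temperatures,
                 summary = sm), class = "temperature_series")
}

#' @export
print.mc_trajectory <- function(x, ...) {
  cat("MC trajectory:", x$config$n_steps, "steps at",
      x$config$temperature, "K,", nrow(x$records), "records\n")
  cat(sprintf("  acceptance ratio: %.1f%%\n", 100 * x$acceptance_ratio))
  invisible(x)
}

#' @export
summary.mc_trajectory <- function(object, ...) {
  r <- object$records
  keep <- r[!r$equil, , drop = FALSE]
  acc <- rbind(proposed = object$proposed, accepted = object$accepted)
  out <- list(acceptance = acc,
              acceptance_ratio = object$acceptance_ratio,
              mean_E = mean(keep$E_total), sd_E = sd(keep$E_total),
              mean_Q = mean(keep$Q), n_records = nrow(r),
              n_equil = sum(r$equil))
  class(out) <- "summary.mc_trajectory"
  out
}

#' @export
print.summary.mc_trajectory <- function(x, ...) {
  cat("Per-kind proposals/acceptances:\n")
  print(x$acceptance)
  cat(sprintf("accumulated acceptance ratio: %.1f%%\n",
              100 * x$acceptance_ratio))
  cat(sprintf("post-equilibration E_total: %.3f (sd %.3f) kcal/mol\n",
              x$mean_E, x$sd_E))
  if (!is.na(x$mean_Q)) cat(sprintf("mean Q: %.3f\n", x$mean_Q))
  invisible(x)
}

#' @export
plot.mc_trajectory <- function(x, ...) {
  r <- x$records
  op <- par(mfrow = c(if (all(is.na(r$Q))) 1 else 2, 1),
            mar = c(4, 4, 1, 1))
  on.exit(par(op))
  plot(r$step, r$E_total, type = "l", xlab = "MC step",
       ylab = "E_total (kcal/mol)", ...)
  if (!all(is.na(r$Q)))
    plot(r$step, r$Q, type = "l", xlab = "MC step", ylab = "Q",
         ylim = c(0, 1), ...)
  invisible(x)
}
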