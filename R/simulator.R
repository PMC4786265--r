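# Reduced-units Langevin dynamics for structure-based Hamiltonians.
# epsilon = 1, k_B = 1, length in nm, default mass 1. The compiled kernels
# live in src/sim.cpp.

#' Dihedral potential F_D
#'
#' `F_D(dphi) = [1 - cos(dphi)] + 1/2 [1 - cos(3 dphi)]`, in units of the
#' dihedral strength. The argument is wrapped to (-pi, pi]. F_D(0) = 0,
#' F_D(pi) = 3.
#'
#' @param dphi deviation from the native dihedral (rad), any real.
#' @return potential value (vectorized).
#' @export
dihedral_potential <- function(dphi) {
  (1 - cos(dphi)) + 0.5 * (1 - cos(3 * dphi))
}

#' Native-contact pair potential
#'
#' Forms: `lj_12_10` is `eps * [5 (r0/r)^12 - 6 (r0/r)^10]` (minimum -eps at
#' r0); `gaussian` is `-eps * exp(-(r - r0)^2 / (2 width^2))`; `harmonic` is
#' `(eps/2) (r - r0)^2` (here `eps` is the spring constant).
#'
#' @param r pair distance (nm), > 0.
#' @param r0 native distance (nm).
#' @param eps contact strength (reduced energy), or spring constant for the
#'   harmonic form.
#' @param form one of "lj_12_10", "gaussian", "harmonic".
#' @param width Gaussian well width (nm), used by the gaussian form.
#' @return potential value (vectorized over `r`).
#' @export
contact_potential <- function(r, r0, eps = 1, form = c("lj_12_10", "gaussian", "harmonic"),
                              width = 0.05) {
  form <- match.arg(form)
  if (any(r <= 0)) stop("contact potential requires r > 0 (overflow guard)", call. = FALSE)
  switch(form,
    lj_12_10 = eps * (5 * (r0 / r)^12 - 6 * (r0 / r)^10),
    gaussian = -eps * exp(-(r - r0)^2 / (2 * width^2)),
    harmonic = 0.5 * eps * (r - r0)^2
  )
}

.check_coords <- function(coords, topology) {
  if (is.null(coords)) stop("no coordinates supplied and topology carries none", call. = FALSE)
  coords <- as.matrix(coords)
  if (!is.numeric(coords) || ncol(coords) != 3L) {
    stop("coords must be a numeric n x 3 matrix", call. = FALSE)
  }
  if (nrow(coords) != nrow(topology$atoms)) stop("coordinate/atom count mismatch", call. = FALSE)
  coords
}

# pack an sbm_topology into the flat list the C++ kernels consume
.pack_topology <- function(topology) {
  t <- topology
  n <- nrow(t$atoms)
  c12 <- t$atomtypes$c12[match(t$atoms$type, t$atomtypes$type)]
  form_code <- c(lj_12_10 = 1, gaussian = 2, harmonic = 3)
  con <- t$contacts
  list(
    mass = as.numeric(t$atoms$mass),
    c12 = as.numeric(c12),
    bonds = cbind(t$bonds$i, t$bonds$j, t$bonds$r0, t$bonds$k),
    angles = cbind(t$angles$i, t$angles$j, t$angles$k, t$angles$theta0, t$angles$ktheta),
    dihedrals = cbind(t$dihedrals$i, t$dihedrals$j, t$dihedrals$k, t$dihedrals$l,
                      t$dihedrals$phi0, t$dihedrals$kd),
    contacts = cbind(con$i, con$j, con$r0, con$eps,
                     unname(form_code[con$form]),
                     ifelse(is.na(con$width), 0, con$width)),
    exclusions = if (nrow(t$exclusions)) {
      matrix(as.integer(t$exclusions), ncol = 2)
    } else matrix(integer(), ncol = 2)
  )
}

#' Potential energy breakdown
#'
#' Evaluates all five Hamiltonian sums at the supplied coordinates: bonds,
#' angles, dihedrals, native contacts and excluded volume (the generic
#' repulsion over all non-excluded, non-contact pairs). Exact, untruncated
#' evaluation (no nonbonded cutoff).
#'
#' @param topology an `sbm_topology`.
#' @param coords n x 3 coordinate matrix (nm); defaults to the topology's
#'   native coordinates.
#' @return list with `bonds`, `angles`, `dihedrals`, `contacts`, `excluded`,
#'   `total` (reduced energy units).
#' @export
compute_energy <- function(topology, coords = topology$coords) {
  coords <- .check_coords(coords, topology)
  out <- .sbm_energy_forces_cpp(coords, .pack_topology(topology), -1, FALSE)
  out$forces <- NULL
  out
}

#' Forces (-gradient of the potential)
#'
#' @inheritParams compute_energy
#' @return n x 3 matrix of forces (reduced energy / nm).
#' @export
compute_forces <- function(topology, coords = topology$coords) {
  coords <- .check_coords(coords, topology)
  .sbm_energy_forces_cpp(coords, .pack_topology(topology), -1, TRUE)$forces
}

#' Simulation parameters
#'
#' @param dt time step (reduced time, default 5e-4; conservative for the
#'   default bond stiffness of 2e4).
#' @param gamma Langevin friction (reduced inverse time, default 1).
#' @param temperature reduced temperature (k_B = 1).
#' @param n_steps number of integration steps.
#' @param save_every save a frame every this many steps.
#' @param seed integer seed fixing the full random stream.
#' @param nb_cutoff excluded-volume cutoff (nm); the potential is shifted to
#'   zero at the cutoff. Set <= 0 for untruncated evaluation.
#' @param skin Verlet-list skin (nm); the list is rebuilt when any atom has
#'   moved more than skin/2 since the last build.
#' @return list of class `sbm_params`.
#' @export
sim_params <- function(dt = 5e-4, gamma = 1.0, temperature = 1.0,
                       n_steps = 1e5, save_every = 1000L, seed = 1L,
                       nb_cutoff = 0.8, skin = 0.25) {
  stopifnot(dt > 0, temperature >= 0, n_steps >= 1, save_every >= 1)
  structure(list(dt = dt, gamma = gamma, temperature = temperature,
                 n_steps = as.numeric(n_steps), save_every = as.integer(save_every),
                 seed = as.integer(seed), nb_cutoff = nb_cutoff, skin = skin),
            class = "sbm_params")
}

#' Run Langevin dynamics
#'
#' BAOAB-splitting Langevin integrator (velocity Verlet in the zero-friction
#' limit). Deterministic given the seed: one counter-based random stream,
#' Gaussian draws in fixed atom order. Initial velocities are drawn from the
#' Maxwell-Boltzmann distribution at the target temperature. Aborts with a
#' diagnostic if any coordinate exceeds 1e6 (blow-up guard).
#'
#' @param topology an `sbm_topology`.
#' @param coords starting coordinates (default: the topology's native
#'   coordinates).
#' @param params an `sbm_params` (see [sim_params()]); further arguments in
#'   `...` override its fields.
#' @param ... overrides for individual [sim_params()] fields.
#' @return an `sbm_trajectory`: list with `frames` (n_atoms x 3 x n_frames
#'   array, nm), `energies` (data.frame with per-frame energy breakdown,
#'   kinetic energy and instantaneous temperature) and `params`.
#' @export
run_langevin <- function(topology, coords = topology$coords, params = sim_params(), ...) {
  coords <- .check_coords(coords, topology)
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(params)) stop("unknown simulation parameter: ", nm, call. = FALSE)
    params[[nm]] <- dots[[nm]]
  }
  params <- do.call(sim_params, unclass(params))
  out <- .sbm_run_langevin_cpp(coords, .pack_topology(topology),
                               params$dt, params$gamma, params$temperature,
                               params$n_steps, params$save_every, params$seed,
                               params$nb_cutoff, params$skin)
  frames <- aperm(out$frames, c(2, 1, 3))  # -> atoms x 3 x frames
  en <- as.data.frame(out$energies)
  names(en) <- c("step", "bonds", "angles", "dihedrals", "contacts", "excluded",
                 "potential", "kinetic")
  en$total <- en$potential + en$kinetic
  dof <- 3 * nrow(coords)
  en$temperature <- 2 * en$kinetic / dof
  structure(list(frames = frames, energies = en, params = params,
                 n_atoms = nrow(coords)),
            class = "sbm_trajectory")
}

#' @export
print.sbm_trajectory <- function(x, ...) {
  nf <- dim(x$frames)[3]
  cat(sprintf("Trajectory: %d atoms, %d frames (every %d steps of dt=%g, T=%g, gamma=%g, seed=%d)\n",
              x$n_atoms, nf, x$params$save_every, x$params$dt,
              x$params$temperature, x$params$gamma, x$params$seed))
  invisible(x)
}

#' Convert a reduced temperature to an mdp temperature
#'
#' With the convention that the reduced energy unit maps to 1 kJ/mol, the
#' simulation-package temperature is `T_reduced / k_B` with
#' k_B = 0.00831451 kJ/(mol K). A reduced temperature of 1.17 maps to about
#' 140.7 K, 0.97 to about 116.7 K.
#'
#' @param t_reduced reduced temperature (>= 0).
#' @return temperature in K as used in an mdp input file.
#' @export
reduced_to_mdp_temperature <- function(t_reduced) {
  if (any(t_reduced < 0)) stop("temperature must be non-negative", call. = FALSE)
  t_reduced / 0.00831451
}

#' Write per-frame energies as TSV
#'
#' @param trajectory an `sbm_trajectory`.
#' @param path output file.
#' @export
write_energy_tsv <- function(trajectory, path) {
  utils::write.table(trajectory$energies, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a trajectory as a multi-frame GRO file
#'
#' @param trajectory an `sbm_trajectory`.
#' @param topology the matching topology (atom names/residues).
#' @param path output file.
#' @export
write_trajectory_gro <- function(trajectory, topology, path) {
  at <- topology$atoms
  nf <- dim(trajectory$frames)[3]
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in seq_len(nf)) {
    xyz <- trajectory$frames[, , fr]
    writeLines(sprintf("frame %d, step %d", fr, trajectory$energies$step[fr]), con)
    writeLines(sprintf("%5d", nrow(at)), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       at$residue %% 100000, substr(at$resname, 1, 5),
                       substr(at$name, 1, 5), seq_len(nrow(at)) %% 100000,
                       xyz[, 1], xyz[, 2], xyz[, 3]), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", 0, 0, 0), con)
  }
  invisible(path)
}
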