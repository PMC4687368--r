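# Short vacuum molecular dynamics: velocity-Verlet integration with
# seeded Maxwell-Boltzmann initial velocities, a linear temperature ramp
# over the heating phase and a Berendsen-style weak-coupling thermostat
# during production (no barostat: vacuum runs have no pressure coupling;
# no periodic boundary conditions).

kinetic_energy <- function(vel, mass) {
  0.5 * sum(mass * rowSums(vel^2)) / ACC_CONV
}

instantaneous_temperature <- function(vel, mass) {
  ndof <- max(1L, 3L * length(mass) - 3L)   # COM motion removed
  2 * kinetic_energy(vel, mass) / (ndof * KB_KCAL)
}

maxwell_boltzmann <- function(mass, temperature) {
  n <- length(mass)
  # sd of each velocity component: sqrt(kB T / m), in A/fs
  sd <- sqrt(KB_KCAL * temperature * ACC_CONV / mass)
  vel <- matrix(stats::rnorm(3L * n), n, 3L) * sd
  # remove centre-of-mass drift
  com <- colSums(vel * mass) / sum(mass)
  vel <- sweep(vel, 2L, com)
  vel
}

#' Run short vacuum molecular dynamics
#'
#' Velocity-Verlet integration at `timestep_fs`.  The system is first
#' heated with a linear target-temperature ramp from ~0 K to
#' `temperature` over `heat_ps`, then run for `production_ps` at constant
#' temperature using Berendsen weak coupling (`tau_ps`).  With
#' `thermostat = FALSE` both phases integrate NVE (used for the
#' energy-conservation checks).  All randomness (initial velocities)
#' derives from `protocol$seed`, so identical protocols give identical
#' trajectories.  Delegation environments (`delegate_water`,
#' `delegate_hydrophobic`) are not simulated: a run description for an
#' external solvated-MD engine is returned instead.
#'
#' @param structure A minimized `pep_structure`.
#' @param topology Matching `pep_topology`.
#' @param protocol An [md_protocol()].
#' @return For vacuum runs, a list with `structure` (final frame),
#'   `trajectory` (list of coordinate matrices, every `stride` steps),
#'   and `summary` (data.frame: time_ps, potential, kinetic, total,
#'   temperature, rms_from_start).  For delegation environments, a list
#'   with class `md_delegation` describing the requested run.
#' @export
run_dynamics <- function(structure, topology, protocol = md_protocol()) {
  if (protocol$environment != "vacuum") {
    return(structure(list(
      environment = protocol$environment,
      note = paste("solvated simulation is delegated to an external MD",
                   "engine; this description, the structure and topology",
                   "specify the requested run"),
      protocol = protocol, structure = structure, topology = topology),
      class = "md_delegation"))
  }
  xyz0 <- coords(structure)
  mass <- topology$params$mass
  dt <- protocol$timestep_fs
  n_heat <- max(0L, round(protocol$heat_ps * 1000 / dt))
  n_prod <- max(0L, round(protocol$production_ps * 1000 / dt))
  n_tot <- n_heat + n_prod
  tau_fs <- protocol$tau_ps * 1000

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(protocol$seed)
  vel <- maxwell_boltzmann(mass, if (protocol$thermostat) 1 else
                                   protocol$temperature)

  xyz <- xyz0
  eg <- energy_gradient(xyz, topology)
  frames <- list()
  summ <- list()
  record <- function(step) {
    ke <- kinetic_energy(vel, mass)
    Ti <- instantaneous_temperature(vel, mass)
    rms <- sqrt(mean(rowSums((xyz - xyz0)^2)))
    summ[[length(summ) + 1L]] <<- data.frame(
      time_ps = step * dt / 1000, potential = eg$energy$total,
      kinetic = ke, total = eg$energy$total + ke, temperature = Ti,
      rms_from_start = rms,
      phase = if (step <= n_heat) "heat" else "production")
    frames[[length(frames) + 1L]] <<- xyz
  }
  record(0L)
  for (step in seq_len(n_tot)) {
    force <- -eg$gradient
    if (any(!is.finite(force))) {
      stop("integration blow-up: non-finite force at step ", step)
    }
    accel <- sweep(force, 1L, mass, "/") * ACC_CONV
    vel <- vel + 0.5 * dt * accel
    xyz <- xyz + dt * vel
    eg <- energy_gradient(xyz, topology)
    if (!is.finite(eg$energy$total)) {
      stop("integration blow-up: non-finite energy at step ", step)
    }
    force <- -eg$gradient
    accel <- sweep(force, 1L, mass, "/") * ACC_CONV
    vel <- vel + 0.5 * dt * accel
    if (protocol$thermostat) {
      t_target <- if (step <= n_heat && n_heat > 0L) {
        protocol$temperature * step / n_heat
      } else {
        protocol$temperature
      }
      Ti <- instantaneous_temperature(vel, mass)
      if (Ti > 1e-8) {
        lambda <- sqrt(pmax(0.5, pmin(
          2, 1 + dt / tau_fs * (t_target / Ti - 1))))
        vel <- vel * lambda
      }
    }
    if (step %% protocol$stride == 0L || step == n_tot) record(step)
  }
  list(structure = set_coords(structure, xyz),
       trajectory = frames,
       summary = do.call(rbind, summ))
}

#' @export
print.md_delegation <- function(x, ...) {
  cat("<md_delegation> environment:", x$environment, "\n ", x$note, "\n")
  invisible(x)
}
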