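# Energy minimization: steepest descent with a backtracking (Armijo) line
# search followed by conjugate gradient (Polak-Ribiere with restarts),
# mirroring the two-stage minimization schedule of the modelling protocol
# (1000 + 1000 steps by default).

#' Molecular-dynamics / minimization protocol settings
#'
#' Defaults reproduce the modelling protocol: 1000 steepest-descent +
#' 1000 conjugate-gradient minimization steps, 50 ps heating to 300 K,
#' user-selectable production length (50/100 ps typical), 1 fs timestep,
#' 300 K, vacuum environment.  `delegate_water` / `delegate_hydrophobic`
#' environments are not simulated in-house; they emit an engine-ready
#' description (see [run_dynamics()]).
#'
#' @param minimize_sd_steps,minimize_cg_steps Minimization step counts.
#' @param heat_ps,production_ps Heating / production durations (ps).
#' @param timestep_fs Integration timestep (fs).
#' @param temperature Target temperature (K).
#' @param environment `"vacuum"`, `"delegate_water"` or
#'   `"delegate_hydrophobic"`.
#' @param thermostat Use the weak-coupling thermostat (disable for NVE).
#' @param tau_ps Thermostat coupling time (ps).
#' @param stride Trajectory frame stride (steps).
#' @param seed Integer seed for the Maxwell-Boltzmann initial velocities.
#' @return An `md_protocol` list.
#' @export
md_protocol <- function(minimize_sd_steps = 1000L,
                        minimize_cg_steps = 1000L,
                        heat_ps = 50, production_ps = 100,
                        timestep_fs = 1, temperature = 300,
                        environment = c("vacuum", "delegate_water",
                                        "delegate_hydrophobic"),
                        thermostat = TRUE, tau_ps = 0.1,
                        stride = 100L, seed = 42L) {
  structure(list(
    minimize_sd_steps = as.integer(minimize_sd_steps),
    minimize_cg_steps = as.integer(minimize_cg_steps),
    heat_ps = heat_ps, production_ps = production_ps,
    timestep_fs = timestep_fs, temperature = temperature,
    environment = match.arg(environment), thermostat = thermostat,
    tau_ps = tau_ps, stride = as.integer(stride), seed = as.integer(seed)),
    class = "md_protocol")
}

#' Minimize the energy of a structure
#'
#' Runs `minimize_sd_steps` of steepest descent with a backtracking line
#' search, then `minimize_cg_steps` of Polak-Ribiere conjugate gradient.
#' The energy trace over accepted steepest-descent steps is
#' non-increasing; iteration stops early when the gradient infinity-norm
#' falls below `gtol` or the step size underflows.
#'
#' @param structure A `pep_structure`.
#' @param topology Matching `pep_topology`.
#' @param protocol An [md_protocol()] (step counts are read from it).
#' @param gtol Gradient infinity-norm convergence threshold
#'   (kcal/mol/Angstrom).
#' @return List with `structure` (minimized), `trace` (data.frame of
#'   step, phase, energy) and `energy` (final `energy_report`).
#' @export
minimize <- function(structure, topology, protocol = md_protocol(),
                     gtol = 1e-6) {
  xyz <- coords(structure)
  eg <- energy_gradient(xyz, topology)
  if (!is.finite(eg$energy$total)) stop("non-finite starting energy")
  trace <- list()
  push <- function(step, phase, e) {
    trace[[length(trace) + 1L]] <<- data.frame(step = step, phase = phase,
                                               energy = e)
  }
  push(0L, "start", eg$energy$total)

  alpha <- 1e-3
  step_no <- 0L
  # steepest descent with Armijo backtracking
  for (it in seq_len(protocol$minimize_sd_steps)) {
    gmax <- max(abs(eg$gradient))
    if (!is.finite(gmax)) stop("non-finite gradient during minimization")
    if (gmax < gtol) break
    dir <- -eg$gradient
    gd <- sum(eg$gradient * dir)
    accepted <- FALSE
    a <- alpha
    for (bt in 1:30) {
      xn <- xyz + a * dir
      en <- energy_gradient(xn, topology, grad = FALSE)$energy$total
      if (is.finite(en) && en <= eg$energy$total + 1e-4 * a * gd) {
        accepted <- TRUE
        break
      }
      a <- a / 2
    }
    if (!accepted) break
    xyz <- xn
    eg <- energy_gradient(xyz, topology)
    alpha <- min(a * 1.5, 1)
    step_no <- step_no + 1L
    push(step_no, "sd", eg$energy$total)
  }

  # conjugate gradient (Polak-Ribiere+, restart on non-descent)
  gprev <- eg$gradient
  dir <- -gprev
  alpha <- 1e-3
  for (it in seq_len(protocol$minimize_cg_steps)) {
    gmax <- max(abs(eg$gradient))
    if (!is.finite(gmax)) stop("non-finite gradient during minimization")
    if (gmax < gtol) break
    gd <- sum(eg$gradient * dir)
    if (gd >= 0) {           # not a descent direction: restart
      dir <- -eg$gradient
      gd <- sum(eg$gradient * dir)
    }
    accepted <- FALSE
    a <- alpha
    for (bt in 1:40) {
      xn <- xyz + a * dir
      en <- energy_gradient(xn, topology, grad = FALSE)$energy$total
      if (is.finite(en) && en <= eg$energy$total + 1e-4 * a * gd) {
        accepted <- TRUE
        break
      }
      a <- a / 2
    }
    if (!accepted) break
    xyz <- xn
    gold <- eg$gradient
    eg <- energy_gradient(xyz, topology)
    beta <- max(0, sum(eg$gradient * (eg$gradient - gold)) /
                  max(sum(gold * gold), 1e-30))
    dir <- -eg$gradient + beta * dir
    alpha <- min(a * 1.5, 1)
    step_no <- step_no + 1L
    push(step_no, "cg", eg$energy$total)
  }

  list(structure = set_coords(structure, xyz),
       trace = do.call(rbind, trace),
       energy = eg$energy)
}
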