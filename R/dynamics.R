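#' Langevin integrator configuration
#'
#' Parameters for the BAOAB-class stochastic velocity-Verlet integrator in
#' reduced units (site mass 1, time unit tau).  With `gamma = 0` the
#' update reduces to plain velocity Verlet (NVE).
#'
#' @param dt timestep in tau (default 0.005).
#' @param gamma friction coefficient in 1/tau (default 1).
#' @param temperature_kT thermostat temperature (default 1).
#' @param n_steps number of steps.
#' @param save_every save a frame every this many steps (0 = only the
#'   initial frame).
#' @param seed integer RNG seed for the thermostat noise.
#' @param log_every record an energy-log row every this many steps
#'   (default: `save_every`).
#' @return An object of class `integrator_config`.
#' @export
integrator_config <- function(dt = 0.005, gamma = 1.0, temperature_kT = 1.0,
                              n_steps = 10000L, save_every = 1000L,
                              seed = 1L, log_every = NULL) {
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (gamma < 0) stop("gamma must be >= 0", call. = FALSE)
  if (n_steps < 0) stop("n_steps must be >= 0", call. = FALSE)
  if (is.null(log_every)) log_every <- save_every
  structure(list(dt = dt, gamma = gamma, temperature_kT = temperature_kT,
                 n_steps = as.integer(n_steps),
                 save_every = as.integer(save_every),
                 log_every = as.integer(log_every),
                 seed = as.integer(seed)),
            class = "integrator_config")
}

#' @export
print.integrator_config <- function(x, ...) {
  cat(sprintf(
    "integrator: dt=%g tau, gamma=%g/tau, kT=%g, %d steps (save every %d), seed %d\n",
    x$dt, x$gamma, x$temperature_kT, x$n_steps, x$save_every, x$seed))
  invisible(x)
}

#' Draw Maxwell-Boltzmann velocities
#'
#' @param system a `cg_system`.
#' @param kT temperature in reduced units.
#' @param seed RNG seed.
#' @return the system with velocities replaced by a fresh draw (zero
#'   centre-of-mass momentum).
#' @export
thermalize_velocities <- function(system, kT = 1.0, seed = 1L) {
  rng <- .make_rng(seed)
  v <- matrix(.with_rng(rng, stats::rnorm(3 * nrow(system$positions))),
              ncol = 3) * sqrt(kT)
  system$velocities <- sweep(v, 2, colMeans(v))
  system
}

.expand_schedule_steps <- function(schedule, n_steps, default_eps) {
  if (is.null(schedule)) return(default_eps)
  if (is.numeric(schedule) && length(schedule) == 1)
    return(as.numeric(schedule))
  if (inherits(schedule, "hydration_schedule"))
    return(schedule_eps_steps(schedule, n_steps))
  if (is.numeric(schedule)) {
    if (length(schedule) != n_steps)
      stop("per-step dielectric vector must have length n_steps",
           call. = FALSE)
    return(as.numeric(schedule))
  }
  stop("schedule must be NULL, a scalar eps_r, a per-step vector, or a hydration_schedule",
       call. = FALSE)
}

#' Run Langevin dynamics
#'
#' Advances the system with the BAOAB integrator.  The solvent dielectric
#' may be held constant (the force field's value), set to another scalar,
#' follow an explicit per-step vector, or follow a [hydration_schedule()];
#' it is updated before each force evaluation.  Runs are bit-reproducible
#' for a fixed seed.
#'
#' @param system a `cg_system`.  If its velocities are all zero they are
#'   first drawn from the Maxwell-Boltzmann distribution at the
#'   integrator temperature (seed derived from `cfg$seed`).
#' @param ff a [force_field()].
#' @param cfg an [integrator_config()].
#' @param schedule dielectric schedule (see Details); `NULL` keeps
#'   `ff$dielectric_eps_r`.
#' @param kT_schedule optional per-step temperature vector (annealing);
#'   defaults to constant `cfg$temperature_kT`.
#' @return An object of class `cg_trajectory`: frames (positions), frame
#'   step indices, per-frame dielectric, energy log, final state and
#'   metadata.  If the integration fails the trajectory is truncated at
#'   the last good frame and carries `ok = FALSE` and the failing step.
#' @export
run_dynamics <- function(system, ff, cfg, schedule = NULL,
                         kT_schedule = NULL) {
  stopifnot(inherits(system, "cg_system"), inherits(ff, "cg_forcefield"),
            inherits(cfg, "integrator_config"))
  .check_box(system, ff)
  eps_steps <- .expand_schedule_steps(schedule, cfg$n_steps,
                                      ff$dielectric_eps_r)
  if (is.null(kT_schedule)) kT_schedule <- cfg$temperature_kT
  if (any(kT_schedule <= 0) || any(!is.finite(kT_schedule)))
    stop("temperature schedule must be positive and finite", call. = FALSE)
  if (!(length(kT_schedule) %in% c(1L, max(cfg$n_steps, 1L))))
    stop("kT_schedule must be scalar or length n_steps", call. = FALSE)
  if (all(system$velocities == 0) && cfg$gamma > 0)
    system <- thermalize_velocities(system, kT_schedule[1],
                                    seed = cfg$seed + 777L)
  m <- .system_meta(system)
  res <- cpp_run_langevin(system$positions, system$velocities, system$box,
                          isTRUE(system$periodic), m$chain, m$mono, m$isS,
                          m$charge, m$bonds, m$angles, unclass(ff),
                          as.numeric(eps_steps), as.numeric(kT_schedule),
                          cfg$dt, cfg$gamma, cfg$n_steps, cfg$save_every,
                          cfg$seed, cfg$log_every)
  final <- system
  final$positions <- res$positions
  final$velocities <- res$velocities
  structure(list(
    frames = res$frames,
    frame_steps = res$frame_steps,
    frame_eps = res$frame_eps,
    log = as.data.frame(res$log),
    final_system = final,
    box = system$box,
    site_role = system$site_role,
    chain_id = system$chain_id,
    monomer_id = system$monomer_id,
    n_chains = system$n_chains, N = system$N,
    forcefield = ff, config = cfg,
    ok = res$ok, fail_step = res$fail_step
  ), class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat(sprintf(
    "CG trajectory: %d frames (steps %d..%d), %d chain(s) x %d monomers%s\n",
    length(x$frames), x$frame_steps[1],
    x$frame_steps[length(x$frame_steps)], x$n_chains, x$N,
    if (isTRUE(x$ok)) "" else sprintf(" [FAILED at step %d]", x$fail_step)))
  cat(sprintf("  eps_r %g -> %g\n", x$frame_eps[1],
              x$frame_eps[length(x$frame_eps)]))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `cg_trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) length(traj$frames)

#' Annealing run with a temperature ramp
#'
#' Convenience wrapper around [run_dynamics()] with a per-step temperature
#' schedule; a flat schedule is identical to a plain run.
#'
#' @param system,ff,cfg as in [run_dynamics()].
#' @param kT_start,kT_end endpoints of a linear ramp over `cfg$n_steps`
#'   steps; or pass `kT_schedule` directly.
#' @param kT_schedule explicit per-step temperature vector (overrides the
#'   linear ramp).
#' @param schedule optional dielectric schedule, as in [run_dynamics()].
#' @return a `cg_trajectory`.
#' @export
anneal <- function(system, ff, cfg, kT_start = 2.0, kT_end = 1.0,
                   kT_schedule = NULL, schedule = NULL) {
  if (is.null(kT_schedule))
    kT_schedule <- if (cfg$n_steps > 0)
      seq(kT_start, kT_end, length.out = cfg$n_steps) else kT_start
  run_dynamics(system, ff, cfg, schedule = schedule,
               kT_schedule = kT_schedule)
}

#' Wrap positions into the primary periodic image
#'
#' @param positions n x 3 matrix.
#' @param box edge lengths.
#' @return matrix with coordinates folded into `[0, box)`.
#' @export
wrap_positions <- function(positions, box) {
  sweep(positions, 2, box, function(x, L) x - L * floor(x / L))
}
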