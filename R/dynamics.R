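#' Langevin dynamics parameters
#'
#' @param dt timestep in reduced ps (default 0.1).
#' @param gamma friction in 1/reduced-ps (default 0.02, the production
#'   value; 0 gives the NVE limit with noise off).
#' @param temperature K.
#' @param seed integer master seed for the counter-based noise stream.
#' @return list of class `cg_langevin_params`.
#' @export
langevin_params <- function(dt = 0.1, gamma = 0.02, temperature = 300,
                            seed = 1) {
  stopifnot(dt > 0, gamma >= 0, temperature >= 0)
  structure(list(dt = dt, gamma = gamma, temperature = temperature,
                 seed = seed), class = "cg_langevin_params")
}

#' Simulation state
#'
#' Coordinates, velocities and the global step index. The step index keys
#' the counter-based noise stream, so restarting from a saved state
#' reproduces the continuation bitwise.
#'
#' @param coords n x 3 matrix; @param velocities n x 3 (default zero).
#' @param step global step index already consumed.
#' @return list of class `cg_state`.
#' @export
sim_state <- function(coords, velocities = NULL, step = 0L) {
  if (is.null(velocities)) velocities <- matrix(0, nrow(coords), 3)
  stopifnot(all(dim(coords) == dim(velocities)))
  structure(list(coords = coords, velocities = velocities,
                 step = as.integer(step)), class = "cg_state")
}

#' One (or a few) Langevin integration steps
#'
#' BAOAB splitting of underdamped Langevin dynamics. With `gamma = 0` the
#' scheme reduces to velocity Verlet and conserves energy; fixed-mask beads
#' never move and keep zero velocity.
#'
#' @param state `cg_state`; @param sys `cg_system`;
#' @param params `cg_langevin_params`; @param nsteps number of steps.
#' @return updated `cg_state`.
#' @export
langevin_step <- function(state, sys, params, nsteps = 1) {
  out <- cpp_run(sys, state$coords, state$velocities, as.integer(nsteps),
                 params$dt, params$gamma, params$temperature,
                 as.numeric(params$seed), state$step, 0L, 0L)
  sim_state(out$coords, out$vels, out$step)
}

#' Run a Langevin trajectory
#'
#' Propagates the system, storing frames and a per-category energy log
#' every `stride` steps and (optionally) a reaction-coordinate sample every
#' `rc_stride` steps when the system defines bias groups.
#'
#' @param sys `cg_system`; @param state `cg_state` (or a coordinate matrix);
#' @param params `cg_langevin_params`; @param nsteps steps to run;
#' @param stride frame/energy output interval; @param rc_stride reaction
#'   coordinate sampling interval (0 = off).
#' @return `cg_trajectory`: `frames` (n x 3 x n_frames array), `steps`,
#'   `energies` (data.frame: step, per-category energies, total, kinetic
#'   temperature), `rc`, `state` (final `cg_state`), `params`.
#' @export
run_simulation <- function(sys, state, params, nsteps, stride = 1000,
                           rc_stride = 0) {
  if (is.matrix(state)) state <- sim_state(state)
  if (nsteps == 0) {
    frames <- array(state$coords, dim = c(nrow(state$coords), 3, 1))
    return(structure(list(frames = frames, steps = state$step,
                          energies = NULL, rc = numeric(0), state = state,
                          params = params), class = "cg_trajectory"))
  }
  out <- cpp_run(sys, state$coords, state$velocities, as.integer(nsteps),
                 params$dt, params$gamma, params$temperature,
                 as.numeric(params$seed), state$step, as.integer(stride),
                 as.integer(rc_stride))
  nf <- dim(out$frames)[3]
  frames <- aperm(out$frames, c(2, 1, 3))   # -> n x 3 x nf
  elog <- as.data.frame(out$elog)
  names(elog) <- c("step", .cat_names, "total", "kin_temperature")
  structure(list(frames = frames, steps = elog$step, energies = elog,
                 rc = out$rc, state = sim_state(out$coords, out$vels,
                                                out$step),
                 params = params),
            class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat("cg_trajectory:", dim(x$frames)[3], "frames of", dim(x$frames)[1],
      "beads; final step", x$state$step, "\n")
  invisible(x)
}

#' Number of frames / frame accessor
#' @param traj `cg_trajectory`; @param f frame index.
#' @export
n_frames <- function(traj) dim(traj$frames)[3]

#' @rdname n_frames
#' @export
get_frame <- function(traj, f) traj$frames[, , f]

#' Write / read a plain-text checkpoint
#'
#' Stores coordinates, velocities and the global step index. Together with
#' the counter-based noise stream this restarts a run bitwise-identically.
#'
#' @param state `cg_state`; @param path file path; @param seed seed to
#'   record alongside the state.
#' @export
write_checkpoint <- function(state, path, seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# p53cg checkpoint v1",
               paste("step", state$step),
               paste("seed", seed),
               paste("n", nrow(state$coords))), con)
  utils::write.table(cbind(state$coords, state$velocities), con,
                     row.names = FALSE, col.names = FALSE)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  lines <- readLines(path, n = 4)
  step <- as.integer(strsplit(lines[2], " ")[[1]][2])
  seed <- as.numeric(strsplit(lines[3], " ")[[1]][2])
  m <- as.matrix(utils::read.table(path, skip = 4))
  st <- sim_state(m[, 1:3, drop = FALSE], m[, 4:6, drop = FALSE], step)
  attr(st, "seed") <- seed
  st
}

#' Draw Maxwell-Boltzmann velocities
#' @param n beads; @param mass per-bead mass; @param temperature K;
#' @param seed RNG seed.
#' @export
thermal_velocities <- function(n, mass = 50, temperature = 300, seed = 1) {
  set.seed(seed)
  matrix(stats::rnorm(3 * n, sd = sqrt(.kB * temperature / mass)), n, 3)
}
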