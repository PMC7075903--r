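# Polydisperse soft harmonic disk model with overdamped active Brownian
# dynamics in a square periodic box. Units: stiffness k, substrate friction
# zeta and mean radius set the energy, time and length scales (k = zeta =
# mean radius = 1 by default).

#' Soft-disk configuration
#'
#' Mechanical state of the polydisperse harmonic disk model: particle centers,
#' radii, box size, contact stiffness and substrate friction. Pairs of disks
#' interact through a one-sided harmonic spring acting when they overlap,
#' optionally extended by a short-range piecewise-linear attractive tail used
#' for experiment-matched runs.
#'
#' @param positions Two-column matrix of particle centers.
#' @param radii Per-particle radii `sigma_i` (> 0).
#' @param box_length Periodic box side: a scalar (square box) or `c(Lx, Ly)`.
#' @param stiffness Contact stiffness `k` (energy / length^2).
#' @param friction Substrate friction `zeta` (force * time / length).
#' @param attraction_eps Relative range of the attractive tail (0 disables it;
#'   0.15 for experiment-matched runs).
#' @return An object of class `soft_disk_config`.
#' @export
soft_disk_config <- function(positions, radii, box_length, stiffness = 1,
                             friction = 1, attraction_eps = 0) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 2L) stop_invalid("positions must be an N x 2 matrix")
  n <- nrow(positions)
  if (n < 2L) stop_invalid("need at least 2 particles")
  if (length(radii) != n || any(radii <= 0)) stop_invalid("radii must be positive, one per particle")
  if (length(box_length) == 1L) box_length <- rep(box_length, 2)
  if (length(box_length) != 2L || any(!is.finite(box_length)) || any(box_length <= 0))
    stop_invalid("box_length must be a positive scalar or c(Lx, Ly)")
  check_scalar(stiffness, "stiffness")
  check_scalar(friction, "friction")
  if (attraction_eps < 0) stop_invalid("attraction_eps must be >= 0")
  positions <- cbind(positions[, 1] %% box_length[1], positions[, 2] %% box_length[2])
  structure(list(positions = positions, radii = as.numeric(radii),
                 box_length = box_length, stiffness = stiffness,
                 friction = friction, attraction_eps = attraction_eps),
            class = "soft_disk_config")
}

#' @export
print.soft_disk_config <- function(x, ...) {
  phi <- sum(pi * x$radii^2) / prod(x$box_length)
  cat(sprintf("Soft-disk configuration: N = %d, box = %.4g x %.4g, phi = %.4g, k = %.3g, zeta = %.3g%s\n",
              nrow(x$positions), x$box_length[1], x$box_length[2], phi, x$stiffness, x$friction,
              if (x$attraction_eps > 0) sprintf(", attractive eps = %.3g", x$attraction_eps) else ""))
  invisible(x)
}

#' Active drive state
#'
#' Per-particle polarity angles together with the active speed `v0` and the
#' persistence time `tau` of the rotational diffusion of the polarity
#' direction (`<eta_i(t) eta_j(t')> = delta_ij delta(t - t') / tau`).
#'
#' @param n_particles Number of particles.
#' @param speed Active speed `v0` (length / time, >= 0).
#' @param persistence Persistence time `tau` (> 0).
#' @param angles Optional initial angles (radians); drawn uniformly otherwise.
#' @return An object of class `active_drive`.
#' @export
active_drive <- function(n_particles, speed, persistence, angles = NULL) {
  if (speed < 0) stop_invalid("speed must be >= 0")
  check_scalar(persistence, "persistence")
  if (is.null(angles)) angles <- runif(n_particles, 0, 2 * pi)
  if (length(angles) != n_particles || any(!is.finite(angles)))
    stop_invalid("angles must be finite, one per particle")
  structure(list(angles = as.numeric(angles), speed = speed,
                 persistence = persistence),
            class = "active_drive")
}

#' Generate a relaxed polydisperse packing
#'
#' Draws radii (uniform on `mean_radius * [1 - w, 1 + w]` by default, with
#' `w` the polydispersity), chooses the box so that
#' `sum(pi sigma_i^2) / L^2` equals the packing fraction (overlap areas are
#' counted once per disk, i.e. double-counted in the total), places particles
#' uniformly at random and relaxes them to a mechanically stable minimum.
#'
#' @param n_particles Number of disks (>= 2).
#' @param packing_fraction Target packing fraction `phi` (> 0); 1 emulates a
#'   confluent sheet.
#' @param polydispersity Relative half-width of the radius distribution
#'   (0 <= w < 1); 0.3 emulates cell-size heterogeneity.
#' @param seed Optional RNG seed for reproducibility.
#' @param mean_radius Mean radius (length unit).
#' @param stiffness Contact stiffness `k`.
#' @param distribution `"uniform"` (default) or `"gaussian"` radius law with
#'   the same mean and relative width (Gaussian truncated at positive radii).
#' @param relax If `TRUE` (default) relax to `max |F_i| < tolerance`.
#' @param tolerance Force residual target of the relaxation, in units of
#'   `k * mean_radius`.
#' @param max_iter Iteration cap for the minimizer.
#' @return A relaxed `soft_disk_config`.
#' @export
generate_packing <- function(n_particles, packing_fraction = 1,
                             polydispersity = 0.3, seed = NULL,
                             mean_radius = 1, stiffness = 1,
                             distribution = c("uniform", "gaussian"),
                             relax = TRUE, tolerance = 1e-8, max_iter = 500000L) {
  if (!is.numeric(n_particles) || n_particles < 2) stop_invalid("n_particles must be >= 2")
  check_scalar(packing_fraction, "packing_fraction")
  if (polydispersity < 0 || polydispersity >= 1) stop_invalid("polydispersity must be in [0, 1)")
  distribution <- match.arg(distribution)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_particles)
  radii <- if (polydispersity == 0) {
    rep(mean_radius, n)
  } else if (distribution == "uniform") {
    runif(n, mean_radius * (1 - polydispersity), mean_radius * (1 + polydispersity))
  } else {
    # matching relative std dev of the uniform law: w / sqrt(3)
    r <- rnorm(n, mean_radius, mean_radius * polydispersity / sqrt(3))
    pmax(r, 0.05 * mean_radius)
  }
  L <- sqrt(sum(pi * radii^2) / packing_fraction)
  pos <- cbind(runif(n, 0, L), runif(n, 0, L))
  cfg <- soft_disk_config(pos, radii, L, stiffness = stiffness)
  if (relax) cfg <- relax_to_minimum(cfg, tolerance = tolerance, max_iter = max_iter)
  cfg
}

#' Potential energy and forces of a soft-disk configuration
#'
#' Total energy `sum_{i<j} k/2 (sigma_i + sigma_j - r_ij)^2` over overlapping
#' pairs (minimum-image convention) and the exact forces `-grad_i E`; the
#' pair force magnitude is `k (sigma_i + sigma_j - r_ij)` along the center
#' line. With `attraction_eps > 0` the contact is extended by a
#' piecewise-linear attractive force out to `(1 + eps)(sigma_i + sigma_j)`.
#'
#' @param config A `soft_disk_config`.
#' @return A list with `energy` (scalar) and `forces` (N x 2 matrix).
#' @export
energy_and_forces <- function(config) {
  stopifnot(inherits(config, "soft_disk_config"))
  res <- .sd_energy_forces(config$positions[, 1], config$positions[, 2],
                           config$radii, config$box_length[1], config$box_length[2],
                           config$stiffness, config$attraction_eps)
  list(energy = res$energy, forces = cbind(res$fx, res$fy))
}

#' Relax a configuration to a mechanically stable minimum
#'
#' Overdamped descent (FIRE-accelerated, energy non-increasing) until the
#' largest per-particle net force falls below `tolerance * k * mean(radii)`.
#'
#' @param config A `soft_disk_config`.
#' @param tolerance Force residual target in units of `k * mean(radii)`.
#' @param max_iter Iteration cap; non-convergence raises a warning carrying
#'   the final residual.
#' @return The relaxed `soft_disk_config`, with attributes `energy`, `fmax`,
#'   `converged` and `iterations`.
#' @export
relax_to_minimum <- function(config, tolerance = 1e-8, max_iter = 500000L) {
  stopifnot(inherits(config, "soft_disk_config"))
  fscale <- config$stiffness * mean(config$radii)
  res <- .sd_fire(config$positions[, 1], config$positions[, 2], config$radii,
                  config$box_length[1], config$box_length[2],
                  config$stiffness, config$attraction_eps,
                  tolerance * fscale, as.integer(max_iter),
                  0.01 * config$friction / config$stiffness)
  if (!res$converged)
    warning(sprintf("relaxation did not reach tolerance: max|F| = %.3g after %d iterations",
                    res$fmax, res$iterations),
            call. = FALSE)
  out <- config
  out$positions <- cbind(res$x, res$y)
  attr(out, "energy") <- res$energy
  attr(out, "fmax") <- res$fmax
  attr(out, "converged") <- res$converged
  attr(out, "iterations") <- res$iterations
  out
}

#' Advance the active Brownian dynamics by one step
#'
#' First-order update `r_i <- r_i + dt (v0 n_i + F_i / zeta)` followed by the
#' polarity update `theta_i <- theta_i + N(0, dt / tau)`. Velocities are the
#' pre-wrap displacement divided by `dt`.
#'
#' @param config A `soft_disk_config`.
#' @param drive An `active_drive` with one angle per particle.
#' @param dt Time step (> 0).
#' @return List with updated `config`, `drive` and the `velocities` matrix.
#' @export
step_active <- function(config, drive, dt) {
  stopifnot(inherits(config, "soft_disk_config"), inherits(drive, "active_drive"))
  check_scalar(dt, "dt")
  res <- .sd_run(config$positions[, 1], config$positions[, 2], drive$angles,
                 config$radii, config$box_length[1], config$box_length[2],
                 config$stiffness, config$attraction_eps,
                 drive$speed, drive$persistence,
                 config$friction, dt, 1L, 1L)
  if (res$n_unstable > 0)
    warning("unstable step: dt * max|F| / zeta exceeds a particle radius", call. = FALSE)
  config$positions <- cbind(res$x, res$y)
  drive$angles <- res$theta
  list(config = config, drive = drive,
       velocities = cbind(res$VX[, 1], res$VY[, 1]))
}

new_trajectory <- function(times, X, Y, XU, YU, VX, VY, TH, radii, box_length,
                           metadata) {
  structure(list(times = times, X = X, Y = Y, XU = XU, YU = YU,
                 VX = VX, VY = VY, TH = TH, radii = radii,
                 box_length = box_length, metadata = metadata),
            class = "active_trajectory")
}

#' @export
print.active_trajectory <- function(x, ...) {
  cat(sprintf("Active trajectory: N = %d particles, %d frames, t in [%.4g, %.4g], box %s\n",
              nrow(x$X), length(x$times), min(x$times), max(x$times),
              paste(signif(x$box_length, 4), collapse = " x ")))
  if (length(x$metadata)) {
    md <- x$metadata[names(x$metadata) %in% c("model", "v0", "tau", "dt", "seed")]
    cat("  ", paste(names(md), unlist(md), sep = " = ", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of frames in a trajectory
#' @param trajectory An `active_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(trajectory) length(trajectory$times)

#' Drop an initial transient from a trajectory
#' @param trajectory An `active_trajectory`.
#' @param discard Time window to drop from the start.
#' @return The truncated trajectory.
#' @export
discard_transient <- function(trajectory, discard) {
  keep <- trajectory$times > discard
  for (f in c("X", "Y", "XU", "YU", "VX", "VY", "TH"))
    trajectory[[f]] <- trajectory[[f]][, keep, drop = FALSE]
  trajectory$times <- trajectory$times[keep]
  trajectory
}

#' Run an active Brownian soft-disk trajectory
#'
#' Integrates the overdamped dynamics with a first-order scheme, saving
#' snapshots (wrapped and unwrapped positions, instantaneous velocities and
#' polarity angles) every `save_every` steps. Deterministic given `seed`.
#'
#' @param config A `soft_disk_config`.
#' @param drive An `active_drive`.
#' @param dt Time step (default 0.01 in natural units).
#' @param n_steps Total number of steps (>= `save_every`).
#' @param save_every Snapshot interval in steps.
#' @param seed Optional RNG seed.
#' @param discard Time window discarded from the start of the returned
#'   trajectory (0 keeps everything).
#' @return An `active_trajectory`.
#' @export
run_trajectory <- function(config, drive, dt = 0.01, n_steps, save_every,
                           seed = NULL, discard = 0) {
  stopifnot(inherits(config, "soft_disk_config"), inherits(drive, "active_drive"))
  if (n_steps < save_every) stop_invalid("n_steps must be >= save_every")
  if (!is.null(seed)) set.seed(seed)
  res <- .sd_run(config$positions[, 1], config$positions[, 2], drive$angles,
                 config$radii, config$box_length[1], config$box_length[2],
                 config$stiffness, config$attraction_eps,
                 drive$speed, drive$persistence,
                 config$friction, dt, as.integer(n_steps), as.integer(save_every))
  if (res$n_unstable > 0)
    warning(sprintf("%d unstable integration substeps (dt * |F| / zeta > min radius)",
                    res$n_unstable), call. = FALSE)
  traj <- new_trajectory(res$times, res$X, res$Y, res$XU, res$YU,
                         res$VX, res$VY, res$TH, config$radii,
                         config$box_length,
                         list(model = "softdisk", v0 = drive$speed,
                              tau = drive$persistence, dt = dt,
                              n_steps = n_steps, save_every = save_every,
                              seed = seed, k = config$stiffness,
                              zeta = config$friction,
                              eps = config$attraction_eps,
                              reference_positions = config$positions))
  if (discard > 0) traj <- discard_transient(traj, discard)
  traj
}

#' Run soft-disk dynamics with steady-state division and extrusion
#'
#' Cell division events occur with per-cell rate `1 / cycle_time`; a daughter
#' is placed at a small offset (0.1 mean radii, random direction) from its
#' parent and overlapping cells push each other apart. When the population
#' exceeds `target_n`, the most compressed cell (largest overlap energy) is
#' extruded, holding N near the target in steady state. Between events the
#' dynamics is the standard active Brownian integration.
#'
#' @param config A `soft_disk_config`.
#' @param drive An `active_drive`.
#' @param cycle_time Mean cell-cycle time `tau_div` (> 0); `Inf` disables
#'   division.
#' @param target_n Population size to hold in steady state.
#' @param dt Time step.
#' @param n_steps Total steps.
#' @param save_every Snapshot interval (snapshots are taken from the
#'   fixed-population segments between events).
#' @param seed Optional RNG seed.
#' @return List with the final `config`, `drive`, the per-segment snapshot
#'   list `frames` (times, positions, velocities) and the population history
#'   `n_history` (time, N).
#' @export
divide_and_extrude <- function(config, drive, cycle_time, target_n,
                               dt = 0.01, n_steps, save_every, seed = NULL) {
  stopifnot(inherits(config, "soft_disk_config"), inherits(drive, "active_drive"))
  if (!is.numeric(cycle_time) || length(cycle_time) != 1L || is.na(cycle_time) ||
      cycle_time <= 0)
    stop_invalid("cycle_time must be > 0 (Inf disables division)")
  if (!is.null(seed)) set.seed(seed)
  step <- 0L
  frames <- list()
  n_hist_t <- numeric(0); n_hist_n <- integer(0)
  sbar <- mean(config$radii)
  while (step < n_steps) {
    n <- nrow(config$positions)
    # steps until next division event: geometric with rate n * dt / cycle_time
    p_ev <- min(1, n * dt / cycle_time)
    n_next <- if (is.finite(cycle_time)) min(rgeom_steps(p_ev), n_steps - step) else n_steps - step
    if (n_next > 0) {
      seg_save <- min(save_every, n_next)
      res <- .sd_run(config$positions[, 1], config$positions[, 2], drive$angles,
                     config$radii, config$box_length[1], config$box_length[2],
                     config$stiffness, config$attraction_eps,
                     drive$speed, drive$persistence,
                     config$friction, dt, as.integer(n_next), as.integer(seg_save))
      config$positions <- cbind(res$x, res$y)
      drive$angles <- res$theta
      keep <- which((seq_along(res$times) * seg_save) %% save_every == 0)
      for (ik in keep)
        frames[[length(frames) + 1L]] <-
          list(time = step * dt + res$times[ik],
               positions = cbind(res$X[, ik], res$Y[, ik]),
               velocities = cbind(res$VX[, ik], res$VY[, ik]),
               radii = config$radii)
      step <- step + n_next
    }
    if (step >= n_steps || !is.finite(cycle_time)) break
    # division: duplicate a random cell at a small offset
    i <- sample.int(nrow(config$positions), 1L)
    ang <- runif(1, 0, 2 * pi)
    newpos <- (config$positions[i, ] + 0.1 * sbar * c(cos(ang), sin(ang))) %% config$box_length[1]
    config$positions <- rbind(config$positions, newpos)
    config$radii <- c(config$radii, config$radii[i])
    drive$angles <- c(drive$angles, runif(1, 0, 2 * pi))
    # extrusion: remove the most compressed cell while over target
    while (nrow(config$positions) > target_n) {
      comp <- per_particle_overlap_energy(config)
      j <- which.max(comp)
      config$positions <- config$positions[-j, , drop = FALSE]
      config$radii <- config$radii[-j]
      drive$angles <- drive$angles[-j]
    }
    step <- step + 1L  # division bookkeeping consumes one step
    n_hist_t <- c(n_hist_t, step * dt)
    n_hist_n <- c(n_hist_n, nrow(config$positions))
  }
  list(config = config, drive = drive, frames = frames,
       n_history = data.frame(time = n_hist_t, n = n_hist_n))
}

# geometric waiting time (number of steps until first success), via R RNG
rgeom_steps <- function(p) {
  if (p <= 0) return(.Machine$integer.max)
  u <- runif(1)
  as.integer(ceiling(log(u) / log(1 - min(p, 1 - 1e-12))))
}

per_particle_overlap_energy <- function(config) {
  x <- config$positions[, 1]; y <- config$positions[, 2]
  n <- length(x); L <- config$box_length; k <- config$stiffness
  e <- numeric(n)
  for (i in seq_len(n)) {
    dx <- min_image(x - x[i], L[1]); dy <- min_image(y - y[i], L[2])
    r <- sqrt(dx^2 + dy^2)
    s <- config$radii + config$radii[i]
    ov <- which(r < s & seq_len(n) != i)
    e[i] <- sum(0.5 * k * (s[ov] - r[ov])^2)
  }
  e
}
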