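#' Bonded forces and potential energy
#'
#' Analytic gradient of the sum of bond terms. Broken breakable bonds
#' contribute nothing. Bonds whose instantaneous extension exceeds their
#' rupture extension are returned (irreversibly) marked broken in the
#' \code{bonds} component; integrators propagate that state.
#'
#' @param system A [particle_system()].
#' @return List with \code{forces} (N x 3, Da*A/ps^2), \code{energy}
#'   (potential, Da*A^2/ps^2) and \code{bonds} (possibly updated list).
#' @export
compute_forces <- function(system) {
  stopifnot(inherits(system, "particle_system"))
  out <- bond_forces(system$positions, system$bonds)
  out
}

# Internal workhorse operating on bare matrices (hot path).
bond_forces <- function(pos, bonds) {
  n <- nrow(pos)
  forces <- matrix(0, n, 3)
  energy <- 0
  nb <- length(bonds)
  if (nb) {
    for (bi in seq_len(nb)) {
      b <- bonds[[bi]]
      if (!b$intact) next
      i <- b$i; j <- b$j
      dr <- pos[j, ] - pos[i, ]
      r <- sqrt(sum(dr * dr))
      if (r < 1e-10) {
        stop(sprintf("singular geometry: particles %d and %d overlap (r = 0)", i, j),
             call. = FALSE)
      }
      x <- r - b$r0
      if (b$kind == "harmonic") {
        dvdr <- b$k * x
        energy <- energy + 0.5 * b$k * x * x
      } else if (b$kind == "morse") {
        e <- exp(-b$a * x)
        dvdr <- 2 * b$D * b$a * (1 - e) * e
        energy <- energy + b$D * (1 - e)^2
      } else { # breakable
        if (x > b$r_break) {
          bonds[[bi]]$intact <- FALSE
          next
        }
        dvdr <- b$k * x
        energy <- energy + 0.5 * b$k * x * x
      }
      fvec <- (-dvdr / r) * dr # force on j
      forces[j, ] <- forces[j, ] + fvec
      forces[i, ] <- forces[i, ] - fvec
    }
  }
  list(forces = forces, energy = energy, bonds = bonds)
}

check_forces_finite <- function(forces) {
  bad <- which(!is.finite(rowSums(forces)))
  if (length(bad)) {
    stop(sprintf("integration blowup: non-finite force on particle %d", bad[1]),
         call. = FALSE)
  }
}

#' Single velocity-Verlet step at constant energy
#'
#' @param system A [particle_system()].
#' @param dt_fs Timestep in fs (> 0).
#' @return The updated system, time advanced by \code{dt_fs}.
#' @export
nve_step <- function(system, dt_fs = 1) {
  if (!is.numeric(dt_fs) || dt_fs <= 0) stop("dt_fs must be > 0", call. = FALSE)
  run_nve(system, duration_fs = dt_fs, dt_fs = dt_fs, record_energy = FALSE)$system
}

#' Constant-energy (NVE) segment
#'
#' Velocity-Verlet integration for \code{duration_fs}, recording the
#' kinetic/potential/total energy each step. These 100 fs segments are
#' the "pulses" of the PUFF cycle; between controller interventions the
#' dynamics is plain Newtonian.
#'
#' @param system A [particle_system()].
#' @param duration_fs Segment length in fs; must be a non-negative
#'   multiple of \code{dt_fs} (0 returns the system unchanged).
#' @param dt_fs Timestep, fs.
#' @param record_energy Record the per-step energy trace? (Skipped in the
#'   controller hot loop.)
#' @return List with \code{system} and, when recorded, \code{energy}: a
#'   data.frame with columns time_ps, kinetic, potential, total
#'   (Da*A^2/ps^2), one row per step plus the initial state.
#' @export
run_nve <- function(system, duration_fs, dt_fs = 1, record_energy = TRUE) {
  stopifnot(inherits(system, "particle_system"))
  if (!is.numeric(dt_fs) || dt_fs <= 0) stop("dt_fs must be > 0", call. = FALSE)
  if (duration_fs < 0) stop("duration_fs must be >= 0", call. = FALSE)
  n_steps <- round(duration_fs / dt_fs)
  if (abs(n_steps * dt_fs - duration_fs) > 1e-9) {
    stop("duration_fs must be a multiple of dt_fs", call. = FALSE)
  }
  dt <- dt_fs * 1e-3 # ps
  pos <- system$positions
  vel <- system$velocities
  m <- system$masses
  bonds <- system$bonds
  inv_m <- 1 / m

  fe <- bond_forces(pos, bonds)
  check_forces_finite(fe$forces)
  bonds <- fe$bonds

  if (record_energy) {
    ke0 <- 0.5 * sum(m * rowSums(vel^2))
    e_time <- numeric(n_steps + 1)
    e_kin <- numeric(n_steps + 1)
    e_pot <- numeric(n_steps + 1)
    e_time[1] <- system$time
    e_kin[1] <- ke0
    e_pot[1] <- fe$energy
  }

  if (n_steps > 0) {
    half_dt_invm <- 0.5 * dt * inv_m
    for (s in seq_len(n_steps)) {
      vel <- vel + fe$forces * half_dt_invm
      pos <- pos + vel * dt
      fe <- bond_forces(pos, bonds)
      check_forces_finite(fe$forces)
      bonds <- fe$bonds
      vel <- vel + fe$forces * half_dt_invm
      if (record_energy) {
        e_time[s + 1] <- system$time + s * dt
        e_kin[s + 1] <- 0.5 * sum(m * rowSums(vel^2))
        e_pot[s + 1] <- fe$energy
      }
    }
  }

  system$positions <- pos
  system$velocities <- vel
  system$bonds <- bonds
  system$time <- system$time + n_steps * dt
  out <- list(system = system)
  if (record_energy) {
    out$energy <- data.frame(
      time_ps = e_time, kinetic = e_kin, potential = e_pot,
      total = e_kin + e_pot
    )
  }
  out
}

#' Langevin (BAOAB) equilibration
#'
#' Thermalises a system at a target temperature with the BAOAB
#' discretisation of Langevin dynamics, optionally returning snapshots at
#' chosen times for use as independent starting points of repeat pulling
#' runs. With the same seed the trajectory (and all snapshots) is
#' bit-reproducible.
#'
#' @param system A [particle_system()].
#' @param temperature Target temperature, K.
#' @param duration_ps Equilibration length, ps (> 0).
#' @param gamma Friction coefficient, 1/ps.
#' @param dt_fs Timestep, fs.
#' @param seed Integer seed for the thermostat noise.
#' @param snapshot_times Times (ps, within [0, duration_ps]) at which to
#'   record snapshot copies of the system.
#' @return List with \code{system}, \code{snapshots} (list, one per
#'   snapshot time, in order) and \code{temperature_trace} (data.frame
#'   time_ps, temperature sampled every 10 steps).
#' @export
langevin_equilibrate <- function(system, temperature = 300, duration_ps = 20,
                                 gamma = 5, dt_fs = 1, seed = 1,
                                 snapshot_times = NULL) {
  stopifnot(inherits(system, "particle_system"))
  if (duration_ps <= 0) stop("duration_ps must be > 0", call. = FALSE)
  if (gamma <= 0) stop("gamma must be > 0", call. = FALSE)
  if (!is.null(snapshot_times)) {
    if (any(snapshot_times < 0 | snapshot_times > duration_ps + 1e-9)) {
      stop("snapshot_times must lie within [0, duration_ps]", call. = FALSE)
    }
    snapshot_times <- sort(snapshot_times)
  }
  set.seed(as.integer(seed))
  dt <- dt_fs * 1e-3
  n_steps <- ceiling(duration_ps / dt - 1e-9)
  kB <- puff_constants()$boltzmann

  pos <- system$positions
  vel <- system$velocities
  m <- system$masses
  n <- length(m)
  bonds <- system$bonds
  inv_m <- 1 / m
  c1 <- exp(-gamma * dt)
  c2 <- sqrt((1 - c1^2) * kB * temperature) * sqrt(inv_m)

  fe <- bond_forces(pos, bonds)
  check_forces_finite(fe$forces)
  bonds <- fe$bonds

  snaps <- list()
  snap_steps <- if (is.null(snapshot_times)) integer(0) else round(snapshot_times / dt)
  # snapshot at t = 0 if requested
  while (length(snap_steps) && snap_steps[1] == 0) {
    system$positions <- pos; system$velocities <- vel
    system$bonds <- bonds
    snaps[[length(snaps) + 1]] <- system
    snap_steps <- snap_steps[-1]
  }

  trace_every <- 10L
  n_trace <- n_steps %/% trace_every
  tr_time <- numeric(n_trace); tr_temp <- numeric(n_trace); ti <- 0L

  half_dt_invm <- 0.5 * dt * inv_m
  t0 <- system$time
  for (s in seq_len(n_steps)) {
    vel <- vel + fe$forces * half_dt_invm         # B
    pos <- pos + vel * (0.5 * dt)                 # A
    xi <- matrix(stats::rnorm(3 * n), n, 3)
    vel <- c1 * vel + c2 * xi                     # O
    pos <- pos + vel * (0.5 * dt)                 # A
    fe <- bond_forces(pos, bonds)
    check_forces_finite(fe$forces)
    bonds <- fe$bonds
    vel <- vel + fe$forces * half_dt_invm         # B
    if (s %% trace_every == 0L) {
      ti <- ti + 1L
      tr_time[ti] <- t0 + s * dt
      tr_temp[ti] <- kinetic_temperature(vel, m, remove_com = TRUE)
    }
    while (length(snap_steps) && snap_steps[1] == s) {
      snap <- system
      snap$positions <- pos; snap$velocities <- vel
      snap$bonds <- bonds; snap$time <- t0 + s * dt
      snaps[[length(snaps) + 1]] <- snap
      snap_steps <- snap_steps[-1]
    }
  }

  system$positions <- pos
  system$velocities <- vel
  system$bonds <- bonds
  system$time <- t0 + n_steps * dt
  list(
    system = system,
    snapshots = snaps,
    temperature_trace = data.frame(time_ps = tr_time[seq_len(ti)],
                                   temperature = tr_temp[seq_len(ti)])
  )
}
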