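#' Anchor groups for pulling
#'
#' Two disjoint, non-empty sets of particle indices between which the
#' pulling axis, relative velocity and impulse forces are defined. The
#' pulling mass M used in the force bookkeeping F = M dV is the combined
#' mass of both groups.
#'
#' @param group1,group2 Integer vectors of particle indices (1-based).
#' @return An object of class \code{anchor_spec}.
#' @export
anchor_spec <- function(group1, group2) {
  group1 <- sort(unique(as.integer(group1)))
  group2 <- sort(unique(as.integer(group2)))
  if (!length(group1) || !length(group2)) {
    stop("both anchor groups must be non-empty", call. = FALSE)
  }
  if (length(intersect(group1, group2))) {
    stop("anchor groups must be disjoint", call. = FALSE)
  }
  structure(list(group1 = group1, group2 = group2), class = "anchor_spec")
}

#' Group and combined pulling masses of an anchor spec
#'
#' @param system A [particle_system()].
#' @param anchors An [anchor_spec()].
#' @return List with \code{M1}, \code{M2} and \code{M = M1 + M2}, Da.
#' @export
anchor_masses <- function(system, anchors) {
  M1 <- sum(system$masses[anchors$group1])
  M2 <- sum(system$masses[anchors$group2])
  list(M1 = M1, M2 = M2, M = M1 + M2)
}

#' PUFF run parameters
#'
#' @param v_target Target separation velocity, A/ps (>= 0; 0 turns the
#'   protocol into a pure velocity clamp that pins the current
#'   separation).
#' @param pulse_fs Pulse (relaxation) duration, fs; must be a positive
#'   multiple of \code{dt_fs}. 100 fs suits wells whose reflection
#'   completes within that time; slower wells need longer pulses.
#' @param dt_fs Integration timestep, fs.
#' @param rescale_temp Inter-pulse velocity-rescale temperature, K, or
#'   \code{NA} to disable the rescale (used for ballistic controls).
#' @param n_pulses Number of pulses.
#' @param seed Integer seed recorded in run manifests (the pulse loop
#'   itself is deterministic; stochasticity enters through the seeded
#'   Langevin equilibration that prepares starting states).
#' @param remove_com_drift After each impulse, subtract the net
#'   centre-of-mass velocity injected when the two anchor groups have
#'   unequal masses. Off by default: the protocol applies equal and
#'   opposite accelerations (not equal and opposite impulses), and the
#'   uncorrected form is the reference behaviour.
#' @return An object of class \code{puff_params}.
#' @export
puff_params <- function(v_target, pulse_fs = 100, dt_fs = 1,
                        rescale_temp = 300, n_pulses = 100, seed = 1,
                        remove_com_drift = FALSE) {
  if (!is.numeric(v_target) || v_target < 0) {
    stop("v_target must be >= 0", call. = FALSE)
  }
  if (pulse_fs <= 0 || abs(round(pulse_fs / dt_fs) * dt_fs - pulse_fs) > 1e-9) {
    stop("pulse_fs must be a positive multiple of dt_fs", call. = FALSE)
  }
  if (n_pulses < 1) stop("n_pulses must be >= 1", call. = FALSE)
  structure(
    list(v_target = v_target, pulse_fs = pulse_fs, dt_fs = dt_fs,
         rescale_temp = rescale_temp, n_pulses = as.integer(n_pulses),
         seed = as.integer(seed), remove_com_drift = isTRUE(remove_com_drift)),
    class = "puff_params"
  )
}

group_com <- function(mat, masses, idx) {
  colSums(mat[idx, , drop = FALSE] * masses[idx]) / sum(masses[idx])
}

#' Pulling axis between the anchor-group centres of mass
#'
#' @param system A [particle_system()].
#' @param anchors An [anchor_spec()].
#' @return List with \code{axis} (unit vector from group1 COM towards
#'   group2 COM) and \code{separation} (COM distance, A).
#' @export
pulling_axis <- function(system, anchors) {
  com1 <- group_com(system$positions, system$masses, anchors$group1)
  com2 <- group_com(system$positions, system$masses, anchors$group2)
  d <- com2 - com1
  sep <- sqrt(sum(d * d))
  if (sep < 1e-9) {
    stop("degenerate pulling axis: anchor-group centres of mass coincide",
         call. = FALSE)
  }
  list(axis = d / sep, separation = sep)
}

#' Relative anchor-group velocity along the pulling axis
#'
#' The projection (V2 - V1) . N12 of the relative COM velocity of group2
#' with respect to group1 onto the pulling axis. Positive values mean
#' the groups are separating.
#'
#' @inheritParams pulling_axis
#' @return Scalar velocity, A/ps.
#' @export
relative_axis_velocity <- function(system, anchors) {
  ax <- pulling_axis(system, anchors)
  v1 <- group_com(system$velocities, system$masses, anchors$group1)
  v2 <- group_com(system$velocities, system$masses, anchors$group2)
  sum((v2 - v1) * ax$axis)
}

#' Apply one constant-momentum impulse
#'
#' Resets the relative axis velocity of the anchor groups to the target
#' value: with dV = v_target - V12,axis, every atom in group2 has its
#' velocity incremented by +0.5 dV N12 and every atom in group1 by
#' -0.5 dV N12. The change is instantaneous, so the momentum change is
#' booked as the applied force F = M dV (M in pN ps^2/A gives F in pN).
#'
#' @inheritParams pulling_axis
#' @param v_target Target separation velocity, A/ps.
#' @param remove_com_drift Subtract the net COM velocity injected by the
#'   impulse (nonzero only for unequal group masses).
#' @return List with \code{system} (updated) and \code{record}: a
#'   one-row data.frame with time_ps, separation, pre_pulse_velocity,
#'   delta_v, applied_force (pN), axis_x/y/z.
#' @export
apply_impulse <- function(system, anchors, v_target, remove_com_drift = FALSE) {
  if (v_target < 0) stop("v_target must be >= 0", call. = FALSE)
  ax <- pulling_axis(system, anchors)
  v_pre <- relative_axis_velocity(system, anchors)
  delta_v <- v_target - v_pre
  kick <- 0.5 * delta_v * ax$axis
  vel <- system$velocities
  vel[anchors$group2, ] <- sweep(vel[anchors$group2, , drop = FALSE], 2, kick, "+")
  vel[anchors$group1, ] <- sweep(vel[anchors$group1, , drop = FALSE], 2, kick, "-")
  if (remove_com_drift) {
    am <- anchor_masses(system, anchors)
    # net momentum injected: 0.5 dV (M2 - M1) along the axis
    p_inj <- 0.5 * delta_v * (am$M2 - am$M1)
    vel <- sweep(vel, 2, (p_inj / sum(system$masses)) * ax$axis, "-")
  }
  system$velocities <- vel
  m_pn <- mass_to_force_units(sum(system$masses[c(anchors$group1, anchors$group2)]))
  record <- data.frame(
    time_ps = system$time,
    separation = ax$separation,
    pre_pulse_velocity = v_pre,
    delta_v = delta_v,
    applied_force = m_pn * delta_v,
    axis_x = ax$axis[1], axis_y = ax$axis[2], axis_z = ax$axis[3]
  )
  list(system = system, record = record)
}

#' Rescale velocities to a target kinetic temperature
#'
#' Removes the centre-of-mass velocity, then multiplies all velocities
#' by sqrt(temp_K / T_current) where T_current is the COM-free kinetic
#' temperature. A system with zero kinetic energy cannot be rescaled and
#' is returned unchanged with a warning.
#'
#' @param system A [particle_system()].
#' @param temp_K Target temperature, K.
#' @return The updated system.
#' @export
rescale_to_temperature <- function(system, temp_K) {
  vel <- system$velocities
  vcom <- colSums(vel * system$masses) / sum(system$masses)
  vel <- sweep(vel, 2, vcom, "-")
  t_now <- kinetic_temperature(vel, system$masses, remove_com = TRUE)
  if (t_now <= 0) {
    if (temp_K > 0) {
      warning("cannot rescale: system has zero kinetic energy", call. = FALSE)
    }
    return(system)
  }
  system$velocities <- vel * sqrt(temp_K / t_now)
  system
}

#' Run a PUFF constant-momentum pulling trajectory
#'
#' The pulse/relax cycle: for each of \code{n_pulses} pulses, (1) record
#' the separation and the pre-pulse relative axis velocity (the raw
#' dynamical response at the end of the previous relaxation), (2)
#' rescale all velocities to the rescale temperature, (3) apply the
#' impulse that resets the relative axis velocity to \code{v_target},
#' and (4) integrate at constant energy for \code{pulse_fs}. The
#' rescale-then-impulse order means the thermostat never distorts the
#' freshly reset velocity. In the pulse records,
#' \code{pre_pulse_velocity} is the raw pre-rescale response while
#' \code{delta_v} (and hence \code{applied_force}) is the reset actually
#' applied, measured against the post-rescale velocity; the two coincide
#' when the rescale is disabled and differ only through the rescale
#' factor otherwise (negligibly so for systems with many degrees of
#' freedom).
#'
#' An integration blowup aborts the run and returns the pulses completed
#' so far with \code{error} set.
#'
#' @param system A [particle_system()], ideally pre-equilibrated with
#'   [langevin_equilibrate()].
#' @param anchors An [anchor_spec()].
#' @param params A [puff_params()].
#' @param snapshot_every Keep a copy of the system every this many
#'   pulses (0 = none; the final system is always kept).
#' @return An object of class \code{puff_trajectory}: list with
#'   \code{params}, \code{anchors}, \code{pulses} (data.frame, one row
#'   per pulse: index, time_ps, separation, pre_pulse_velocity, delta_v,
#'   applied_force, axis_x/y/z), \code{snapshots}, \code{final_system},
#'   \code{pulling_mass_da} and \code{error} (NULL or message).
#' @export
run_puff <- function(system, anchors, params, snapshot_every = 0) {
  stopifnot(inherits(system, "particle_system"),
            inherits(anchors, "anchor_spec"),
            inherits(params, "puff_params"))
  n <- params$n_pulses
  records <- vector("list", n)
  snapshots <- list()
  err <- NULL
  do_rescale <- !is.na(params$rescale_temp)
  for (p in seq_len(n)) {
    step_result <- tryCatch({
      # raw dynamical response at the end of the previous relaxation,
      # sampled before the thermostat touches the velocities
      v_raw <- relative_axis_velocity(system, anchors)
      if (do_rescale) system <- rescale_to_temperature(system, params$rescale_temp)
      imp <- apply_impulse(system, anchors, params$v_target,
                           remove_com_drift = params$remove_com_drift)
      # delta_v (and the booked force) reflect the reset actually
      # applied, i.e. relative to the post-rescale velocity; the
      # recorded pre-pulse velocity is the raw pre-rescale response.
      # The two coincide when the rescale is disabled and differ only
      # through the rescale factor otherwise.
      imp$record$pre_pulse_velocity <- v_raw
      system <- imp$system
      nv <- run_nve(system, duration_fs = params$pulse_fs,
                    dt_fs = params$dt_fs, record_energy = FALSE)
      list(system = nv$system, record = imp$record)
    }, error = function(e) e)
    if (inherits(step_result, "error")) {
      err <- conditionMessage(step_result)
      records <- records[seq_len(p - 1)]
      break
    }
    system <- step_result$system
    records[[p]] <- step_result$record
    if (snapshot_every > 0 && p %% snapshot_every == 0) {
      snapshots[[length(snapshots) + 1]] <- system
    }
  }
  pulses <- do.call(rbind, records)
  if (!is.null(pulses) && nrow(pulses)) pulses$index <- seq_len(nrow(pulses))
  am <- anchor_masses(system, anchors)
  structure(
    list(params = params, anchors = anchors,
         pulses = pulses[, c("index", setdiff(names(pulses), "index"))],
         snapshots = snapshots, final_system = system,
         pulling_mass_da = am$M, error = err),
    class = "puff_trajectory"
  )
}

#' @export
print.puff_trajectory <- function(x, ...) {
  np <- if (is.null(x$pulses)) 0L else nrow(x$pulses)
  cat(sprintf(paste0(
    "<puff_trajectory> v_target = %.3g A/ps, %d pulses of %g fs, ",
    "pulling mass %.6g Da\n"),
    x$params$v_target, np, x$params$pulse_fs, x$pulling_mass_da))
  if (np) {
    cat(sprintf("  separation %.4g -> %.4g A; max |applied force| %.5g pN\n",
                x$pulses$separation[1], x$pulses$separation[np],
                max(abs(x$pulses$applied_force))))
  }
  if (!is.null(x$error)) cat("  ABORTED:", x$error, "\n")
  invisible(x)
}

#' Theoretical maximum PUFF force
#'
#' When a run is fully trapped the pre-pulse velocity reflects to
#' -v_target, so the largest velocity change any pulse can apply is
#' 2 v_target and the applied force is capped at F_max = 2 M v_target.
#'
#' @param mass Pulling mass: Da by default, or already-converted
#'   pN ps^2/A with \code{mass_units = "pN_ps2_A"}.
#' @param v_target Target velocity, A/ps.
#' @param mass_units Units of \code{mass}.
#' @return Force cap in pN (full precision).
#' @export
theoretical_max_force <- function(mass, v_target,
                                  mass_units = c("Da", "pN_ps2_A")) {
  mass_units <- match.arg(mass_units)
  if (any(mass < 0) || any(v_target < 0)) {
    stop("mass and v_target must be non-negative", call. = FALSE)
  }
  m_pn <- if (mass_units == "Da") mass_to_force_units(mass) else mass
  2 * m_pn * v_target
}
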