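#' Steered-MD baseline: moving harmonic restraint on the separation
#'
#' The conventional constant-velocity pulling control against which the
#' constant-momentum protocol is contrasted. A harmonic spring of
#' stiffness \code{spring_k} acts on the anchor-group separation s, with
#' its target moving at the cantilever velocity: V = k/2 (s - s_t(t))^2,
#' s_t(t) = s(0) + v t. The restraint force k (s_t - s) is distributed
#' over the anchor atoms mass-weighted within each group (equal and
#' opposite between groups), and the instantaneous spring extension and
#' force are logged every step. Because the spring keeps loading while
#' the system resists, its peak force on a trapped system grows far
#' beyond the capped impulse force of the constant-momentum protocol at
#' the same velocity.
#'
#' @param system A [particle_system()].
#' @param anchors An [anchor_spec()].
#' @param spring_k Spring constant, Da/ps^2 (> 0).
#' @param cantilever_velocity Target-point velocity, A/ps.
#' @param duration_ps Run length, ps.
#' @param dt_fs Timestep, fs.
#' @return An object of class \code{smd_trajectory}: list with
#'   \code{log} (data.frame: time_ps, separation, target, extension,
#'   force_pn -- spring force, positive = pulling outward),
#'   \code{final_system}, \code{spring_k}, \code{cantilever_velocity}.
#' @export
run_smd_baseline <- function(system, anchors, spring_k, cantilever_velocity,
                             duration_ps, dt_fs = 1) {
  stopifnot(inherits(system, "particle_system"),
            inherits(anchors, "anchor_spec"))
  if (spring_k <= 0) stop("spring_k must be > 0", call. = FALSE)
  dt <- dt_fs * 1e-3
  n_steps <- round(duration_ps / dt)
  pos <- system$positions
  vel <- system$velocities
  m <- system$masses
  bonds <- system$bonds
  inv_m <- 1 / m
  g1 <- anchors$group1; g2 <- anchors$group2
  w1 <- m[g1] / sum(m[g1]); w2 <- m[g2] / sum(m[g2])
  to_pn <- puff_constants()$force_per_da_accel

  s0 <- pulling_axis(system, anchors)$separation
  restraint <- function(pos, t_ps) {
    com1 <- group_com(pos, m, g1)
    com2 <- group_com(pos, m, g2)
    d <- com2 - com1
    sep <- sqrt(sum(d * d))
    axis <- d / sep
    target <- s0 + cantilever_velocity * t_ps
    fmag <- spring_k * (target - sep) # >0 pulls the groups apart
    list(sep = sep, target = target, fmag = fmag, axis = axis)
  }
  total_force <- function(pos, t_ps) {
    fe <- bond_forces(pos, bonds)
    rs <- restraint(pos, t_ps)
    f <- fe$forces
    f[g2, ] <- f[g2, ] + outer(w2, rs$fmag * rs$axis)
    f[g1, ] <- f[g1, ] - outer(w1, rs$fmag * rs$axis)
    list(forces = f, bonds = fe$bonds, rs = rs)
  }

  log_time <- numeric(n_steps + 1)
  log_sep <- numeric(n_steps + 1)
  log_target <- numeric(n_steps + 1)
  log_force <- numeric(n_steps + 1)

  t_ps <- system$time
  tf <- total_force(pos, 0)
  check_forces_finite(tf$forces)
  bonds <- tf$bonds
  log_time[1] <- t_ps; log_sep[1] <- tf$rs$sep
  log_target[1] <- tf$rs$target; log_force[1] <- tf$rs$fmag * to_pn

  half_dt_invm <- 0.5 * dt * inv_m
  for (s in seq_len(n_steps)) {
    vel <- vel + tf$forces * half_dt_invm
    pos <- pos + vel * dt
    tf <- total_force(pos, s * dt)
    check_forces_finite(tf$forces)
    bonds <- tf$bonds
    vel <- vel + tf$forces * half_dt_invm
    log_time[s + 1] <- t_ps + s * dt
    log_sep[s + 1] <- tf$rs$sep
    log_target[s + 1] <- tf$rs$target
    log_force[s + 1] <- tf$rs$fmag * to_pn
  }

  system$positions <- pos
  system$velocities <- vel
  system$bonds <- bonds
  system$time <- t_ps + n_steps * dt
  structure(
    list(
      log = data.frame(time_ps = log_time, separation = log_sep,
                       target = log_target,
                       extension = log_target - log_sep,
                       force_pn = log_force),
      final_system = system, spring_k = spring_k,
      cantilever_velocity = cantilever_velocity
    ),
    class = "smd_trajectory"
  )
}

#' @export
print.smd_trajectory <- function(x, ...) {
  cat(sprintf(
    "<smd_trajectory> k = %g Da/ps^2, v = %g A/ps, %d steps, peak force %.5g pN\n",
    x$spring_k, x$cantilever_velocity, nrow(x$log) - 1, max(x$log$force_pn)))
  invisible(x)
}
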