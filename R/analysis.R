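#' Least-squares slope of separation versus time
#'
#' Fits an ordinary least-squares line to the per-pulse anchor
#' separation over time; on an unimpeded run the slope recovers the
#' target velocity.
#'
#' @param trajectory A \code{puff_trajectory}.
#' @param window Optional time window \code{c(from, to)} in ps (default:
#'   whole trajectory).
#' @return Slope in A/ps.
#' @export
fit_separation_slope <- function(trajectory, window = NULL) {
  p <- trajectory_pulses(trajectory)
  if (!is.null(window)) {
    p <- p[p$time_ps >= window[1] & p$time_ps <= window[2], ]
  }
  if (nrow(p) < 3) {
    stop("insufficient data: need at least 3 pulses to fit a slope",
         call. = FALSE)
  }
  unname(stats::coef(stats::lm(separation ~ time_ps, data = p))[2])
}

#' Low-pass FFT filter of a per-pulse force series
#'
#' Reproduces the analysis used on raw pulse-force traces: forward real
#' FFT, zero every component whose period is shorter than
#' \code{cutoff_pulses} samples, inverse transform. The slow envelope
#' (the shape whose maximum estimates the unfolding force) survives
#' while per-pulse fluctuation is removed. The DC component is always
#' kept, so a constant series passes through unchanged.
#'
#' @param forces Numeric series (one value per pulse), length >= 4.
#' @param cutoff_pulses Shortest period (in pulses) to keep; >= 2.
#' @return List with \code{smoothed} (same length) and \code{max}.
#' @export
smooth_force_curve <- function(forces, cutoff_pulses = 20) {
  n <- length(forces)
  if (n < 4) stop("force series must have at least 4 samples", call. = FALSE)
  if (cutoff_pulses < 2) {
    stop("invalid cutoff: the shortest resolvable period is 2 samples",
         call. = FALSE)
  }
  spec <- stats::fft(forces)
  k <- seq_len(n) - 1
  cycles <- pmin(k, n - k)        # cycles over the series, 0 = DC
  keep <- cycles <= n / cutoff_pulses # period n/cycles >= cutoff
  spec[!keep] <- 0
  smoothed <- Re(stats::fft(spec, inverse = TRUE)) / n
  list(smoothed = smoothed, max = max(smoothed))
}

#' Mean pre-pulse velocity of a trajectory
#'
#' The average relative axis velocity measured just before each impulse,
#' after discarding an initial burn-in. A persistently negative value is
#' the signature of a trapped system reflecting off a barrier; an
#' unimpeded system averages near +v_target.
#'
#' @param trajectory A \code{puff_trajectory}.
#' @param burn_in_pulses Pulses to discard (default: 10\% of the run).
#' @return Mean velocity, A/ps.
#' @export
mean_pre_pulse_velocity <- function(trajectory, burn_in_pulses = NULL) {
  p <- trajectory_pulses(trajectory)
  if (is.null(burn_in_pulses)) burn_in_pulses <- floor(nrow(p) / 10)
  if (burn_in_pulses >= nrow(p)) {
    stop("insufficient data: burn-in discards every pulse", call. = FALSE)
  }
  mean(p$pre_pulse_velocity[(burn_in_pulses + 1):nrow(p)])
}

#' Classify the response regime of a pulling trajectory
#'
#' Four regimes of response to constant-momentum pulling, identified
#' from the extension ratio r = (final - initial separation) /
#' (v_target * total time):
#' \describe{
#'   \item{saturated}{fully extended early: separation reaches 95\% of
#'     the contour length before the last 10\% of the run;}
#'   \item{constant_momentum}{unfolding at the target rate, r >= 0.8;}
#'   \item{intermittent}{partial extension, 0.1 <= r < 0.8;}
#'   \item{trapped}{no extension, r < 0.1 (and by convention any run
#'     with v_target = 0).}
#' }
#'
#' @param trajectory A \code{puff_trajectory}.
#' @param v_target Target velocity of the run, A/ps (default: taken from
#'   the trajectory parameters).
#' @param contour_length Fully extended anchor separation, A; \code{NA}
#'   disables the saturation test.
#' @return List with \code{regime} (character) and \code{r}.
#' @export
classify_regime <- function(trajectory, v_target = NULL, contour_length = NA) {
  p <- trajectory_pulses(trajectory)
  if (is.null(v_target)) v_target <- trajectory$params$v_target
  total_time <- p$time_ps[nrow(p)] - p$time_ps[1] +
    trajectory$params$pulse_fs * 1e-3
  if (v_target == 0) {
    return(list(regime = "trapped", r = 0))
  }
  r <- (p$separation[nrow(p)] - p$separation[1]) / (v_target * total_time)
  r <- max(r, 0)
  if (!is.na(contour_length)) {
    hit <- which(p$separation >= 0.95 * contour_length)
    if (length(hit) &&
        p$time_ps[hit[1]] <= p$time_ps[1] + 0.9 * total_time) {
      return(list(regime = "saturated", r = r))
    }
  }
  regime <- if (r >= 0.8) "constant_momentum"
            else if (r >= 0.1) "intermittent"
            else "trapped"
  list(regime = regime, r = r)
}

#' Critical velocity from a sweep of regime labels
#'
#' The boundary between the intermittent and constant-momentum ranges:
#' the smallest grid velocity labelled constant_momentum such that every
#' larger, non-saturated velocity is also constant_momentum. Reported at
#' grid resolution (no interpolation).
#'
#' @param sweep A \code{puff_sweep} or a data.frame with columns
#'   \code{v_target} and \code{regime}.
#' @return Critical velocity, A/ps.
#' @export
estimate_critical_velocity <- function(sweep) {
  s <- if (inherits(sweep, "puff_sweep")) sweep$per_velocity else sweep
  s <- s[order(s$v_target), ]
  live <- s[s$regime != "saturated", ]
  if (!nrow(live) || !any(live$regime == "constant_momentum")) {
    stop("boundary not bracketed: no constant_momentum velocity in the sweep",
         call. = FALSE)
  }
  is_cm <- live$regime == "constant_momentum"
  # smallest v from which every larger pre-saturation v is constant_momentum
  all_cm_above <- rev(cumprod(rev(is_cm))) == 1
  v_crit <- live$v_target[which(all_cm_above)[1]]
  if (all(is_cm)) {
    warning(paste("boundary unresolved: every swept velocity is",
                  "constant_momentum; the critical velocity is at or below",
                  "the smallest grid value"), call. = FALSE)
  }
  v_crit
}

#' Unfolding force from the critical velocity
#'
#' F_unfold = 2 M v_critical, the force cap at the smallest target
#' velocity at which unfolding proceeds unimpeded. Reported rounded to
#' the nearest pN (e.g. M = 44 pN ps^2/A, v = 1.8 A/ps -> 158 pN).
#'
#' @param mass Pulling mass, in pN ps^2/A by default (use
#'   \code{mass_units = "Da"} for a mass in dalton).
#' @param v_critical Critical velocity, A/ps.
#' @param mass_units Units of \code{mass}.
#' @return Unfolding force, pN, rounded to the nearest integer.
#' @export
unfolding_force <- function(mass, v_critical,
                            mass_units = c("pN_ps2_A", "Da")) {
  mass_units <- match.arg(mass_units)
  if (any(mass <= 0) || any(v_critical <= 0)) {
    stop("mass and v_critical must be positive", call. = FALSE)
  }
  m_pn <- if (mass_units == "Da") mass_to_force_units(mass) else mass
  round(2 * m_pn * v_critical)
}

#' Force-response curve of a sweep
#'
#' Pairs the maximum smoothed force of each trajectory with the
#' theoretical cap 2 M v_target, and reports the deviation point: the
#' smallest velocity at which the simulated maximum falls below 80\% of
#' the cap, i.e. where the system stops resisting at full strength. The
#' cap at the deviation point is an alternative critical-force
#' estimate.
#'
#' @param sweep A \code{puff_sweep}.
#' @return List with \code{curve} (data.frame: v_target,
#'   max_smoothed_force, theoretical_max), \code{deviation_velocity} and
#'   \code{deviation_force} (pN; NA when the sweep never deviates).
#' @export
force_response_curve <- function(sweep) {
  stopifnot(inherits(sweep, "puff_sweep"))
  s <- sweep$per_velocity[order(sweep$per_velocity$v_target), ]
  theo <- theoretical_max_force(sweep$pulling_mass_da, s$v_target)
  curve <- data.frame(
    v_target = s$v_target,
    max_smoothed_force = s$max_smoothed_force,
    theoretical_max = theo
  )
  dev_idx <- which(curve$max_smoothed_force < 0.8 * curve$theoretical_max)
  dev_v <- if (length(dev_idx)) curve$v_target[dev_idx[1]] else NA_real_
  dev_f <- if (length(dev_idx)) {
    theoretical_max_force(sweep$pulling_mass_da, dev_v)
  } else NA_real_
  list(curve = curve, deviation_velocity = dev_v, deviation_force = dev_f)
}

#' Detect distance plateaus (candidate unfolding intermediates)
#'
#' Finds maximal time intervals over which the anchor separation stays
#' within \code{tolerance_A} of the interval mean for at least
#' \code{min_duration_ps}. Each plateau is classified by its extension:
#' \code{folded} if its mean lies within the tolerance of the initial
#' separation, \code{unfolded} if it lies at or beyond 95\% of the
#' contour length (when given), otherwise \code{intermediate} -- a
#' metastable, partially extended state.
#'
#' @param trajectory A \code{puff_trajectory}.
#' @param min_duration_ps Minimum plateau duration, ps (default: 20\% of
#'   the run).
#' @param tolerance_A Allowed deviation from the plateau mean, A.
#' @param contour_length Fully extended separation, A (NA: no
#'   \code{unfolded} classification).
#' @return A data.frame of class \code{plateau_report} with columns
#'   start_ps, end_ps, mean_extension (A) and classification; zero rows
#'   when no plateau qualifies.
#' @export
detect_plateaus <- function(trajectory, min_duration_ps = NULL,
                            tolerance_A = 2, contour_length = NA) {
  p <- trajectory_pulses(trajectory)
  run_span <- p$time_ps[nrow(p)] - p$time_ps[1]
  if (is.null(min_duration_ps)) min_duration_ps <- 0.2 * run_span
  if (run_span <= min_duration_ps) {
    stop("trajectory shorter than the minimum plateau duration", call. = FALSE)
  }
  sep <- p$separation
  t <- p$time_ps
  n <- length(sep)
  initial <- sep[1]

  out <- list()
  i <- 1L
  while (i <= n) {
    j <- i
    lo <- sep[i]; hi <- sep[i]; s <- sep[i]
    while (j < n) {
      lo2 <- min(lo, sep[j + 1]); hi2 <- max(hi, sep[j + 1])
      s2 <- s + sep[j + 1]
      mu <- s2 / (j + 1 - i + 1)
      if (hi2 - mu <= tolerance_A && mu - lo2 <= tolerance_A) {
        j <- j + 1L; lo <- lo2; hi <- hi2; s <- s2
      } else break
    }
    if (t[j] - t[i] >= min_duration_ps) {
      mu <- s / (j - i + 1)
      cls <- if (mu - initial < tolerance_A) "folded"
             else if (!is.na(contour_length) && mu >= 0.95 * contour_length)
               "unfolded"
             else "intermediate"
      out[[length(out) + 1]] <- data.frame(
        start_ps = t[i], end_ps = t[j], mean_extension = mu,
        classification = cls
      )
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  # Merge adjacent plateaus at the same level: a drifting or briefly
  # interrupted metastable state is one plateau, not several. Two
  # intervals are merged when the gap between them is shorter than the
  # minimum duration and their means differ by no more than the
  # tolerance; the merged mean is recomputed from the series.
  if (length(out) > 1) {
    merged <- list(out[[1]])
    for (k in 2:length(out)) {
      last <- merged[[length(merged)]]
      nxt <- out[[k]]
      if (nxt$start_ps - last$end_ps <= min_duration_ps &&
          abs(nxt$mean_extension - last$mean_extension) <= tolerance_A) {
        sel <- t >= last$start_ps & t <= nxt$end_ps
        last$end_ps <- nxt$end_ps
        last$mean_extension <- mean(sep[sel])
        merged[[length(merged)]] <- last
      } else {
        merged[[length(merged) + 1]] <- nxt
      }
    }
    out <- merged
    for (k in seq_along(out)) {
      mu <- out[[k]]$mean_extension
      out[[k]]$classification <-
        if (mu - initial < tolerance_A) "folded"
        else if (!is.na(contour_length) && mu >= 0.95 * contour_length)
          "unfolded"
        else "intermediate"
    }
  }
  rep <- if (length(out)) do.call(rbind, out) else
    data.frame(start_ps = numeric(0), end_ps = numeric(0),
               mean_extension = numeric(0), classification = character(0))
  class(rep) <- c("plateau_report", "data.frame")
  rep
}

#' Sweep a fixture over a grid of target velocities
#'
#' Runs one PUFF trajectory per grid velocity, summarises each (mean
#' pre-pulse velocity, maximum smoothed force, extension ratio, regime),
#' and estimates the critical velocity and unfolding force for the
#' sweep. Passing several starting systems (snapshots of one
#' equilibration) cycles them over the grid, so a single atypical
#' starting conformation perturbs isolated grid points rather than a
#' contiguous block -- an isolated misclassification cannot move the
#' regime boundary.
#'
#' @param system Starting [particle_system()] (shared across the grid),
#'   or a list of systems to cycle over the grid points.
#' @param anchors An [anchor_spec()].
#' @param v_grid Strictly increasing grid of target velocities, A/ps.
#' @param contour_length Contour length for regime classification, A.
#' @param pulse_fs,dt_fs,rescale_temp,n_pulses,seed Per-run parameters,
#'   as in [puff_params()].
#' @param cutoff_pulses Low-pass filter cutoff for the force curves.
#' @return An object of class \code{puff_sweep}: list with
#'   \code{per_velocity} (data.frame: v_target, mean_pre_pulse_velocity,
#'   max_smoothed_force, r, regime), \code{v_critical} (NA when the
#'   boundary is not bracketed), \code{f_unfold_pn},
#'   \code{pulling_mass_da}, \code{contour_length} and
#'   \code{trajectories} (kept only when \code{keep_trajectories}).
#' @param keep_trajectories Keep the full per-velocity trajectories?
#' @export
run_velocity_sweep <- function(system, anchors, v_grid, contour_length = NA,
                               pulse_fs = 100, dt_fs = 1, rescale_temp = 300,
                               n_pulses = 100, seed = 1, cutoff_pulses = 20,
                               keep_trajectories = FALSE) {
  if (length(v_grid) < 3) stop("need a grid of at least 3 velocities", call. = FALSE)
  if (any(diff(v_grid) <= 0)) stop("v_grid must be strictly increasing", call. = FALSE)
  starts <- if (inherits(system, "particle_system")) list(system) else system
  for (s in starts) stopifnot(inherits(s, "particle_system"))
  rows <- vector("list", length(v_grid))
  trajs <- if (keep_trajectories) vector("list", length(v_grid)) else NULL
  for (iv in seq_along(v_grid)) {
    v <- v_grid[iv]
    start <- starts[[(iv - 1) %% length(starts) + 1]]
    traj <- run_puff(start, anchors,
                     puff_params(v_target = v, pulse_fs = pulse_fs,
                                 dt_fs = dt_fs, rescale_temp = rescale_temp,
                                 n_pulses = n_pulses, seed = seed))
    if (!is.null(traj$error)) {
      warning(sprintf("run at v_target = %g aborted: %s", v, traj$error),
              call. = FALSE)
    }
    cls <- classify_regime(traj, v, contour_length)
    rows[[iv]] <- data.frame(
      v_target = v,
      mean_pre_pulse_velocity = mean_pre_pulse_velocity(traj),
      max_smoothed_force =
        smooth_force_curve(traj$pulses$applied_force, cutoff_pulses)$max,
      r = cls$r,
      regime = cls$regime
    )
    if (keep_trajectories) trajs[[iv]] <- traj
  }
  per_velocity <- do.call(rbind, rows)
  am <- anchor_masses(starts[[1]], anchors)
  v_crit <- tryCatch(estimate_critical_velocity(per_velocity),
                     error = function(e) {
                       warning(conditionMessage(e), call. = FALSE)
                       NA_real_
                     })
  f_unfold <- if (is.na(v_crit)) NA_real_ else
    unfolding_force(am$M, v_crit, mass_units = "Da")
  structure(
    list(per_velocity = per_velocity, v_critical = v_crit,
         f_unfold_pn = f_unfold, pulling_mass_da = am$M,
         contour_length = contour_length, trajectories = trajs),
    class = "puff_sweep"
  )
}

#' @export
print.puff_sweep <- function(x, ...) {
  cat(sprintf("<puff_sweep> %d velocities, pulling mass %.6g Da\n",
              nrow(x$per_velocity), x$pulling_mass_da))
  print(x$per_velocity, row.names = FALSE)
  if (!is.na(x$v_critical)) {
    cat(sprintf("v_critical = %g A/ps -> F_unfold = %g pN\n",
                x$v_critical, x$f_unfold_pn))
  } else {
    cat("v_critical not bracketed by the grid\n")
  }
  invisible(x)
}

# Shared accessor with the insufficient-data guard.
trajectory_pulses <- function(trajectory) {
  stopifnot(inherits(trajectory, "puff_trajectory"))
  p <- trajectory$pulses
  if (is.null(p) || !nrow(p)) {
    stop("trajectory contains no pulses", call. = FALSE)
  }
  p
}
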