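#' Plot a pulling trajectory (distance, velocity, force panels)
#'
#' Three stacked panels over time: anchor separation, pre-pulse
#' velocity (with the target velocity as a dashed reference), and the
#' raw applied force with its low-pass-smoothed envelope.
#'
#' @param x A \code{puff_trajectory}.
#' @param cutoff_pulses Low-pass filter cutoff for the force panel.
#' @param ... Passed to \code{plot}.
#' @return \code{x}, invisibly.
#' @export
plot.puff_trajectory <- function(x, cutoff_pulses = 20, ...) {
  p <- trajectory_pulses(x)
  old <- graphics::par(mfrow = c(3, 1), mar = c(4, 4.2, 1, 1))
  on.exit(graphics::par(old))
  graphics::plot(p$time_ps, p$separation, type = "l",
                 xlab = "time (ps)", ylab = "separation (A)", ...)
  graphics::plot(p$time_ps, p$pre_pulse_velocity, type = "l",
                 xlab = "time (ps)", ylab = "pre-pulse velocity (A/ps)", ...)
  graphics::abline(h = x$params$v_target, lty = 2, col = "grey40")
  graphics::abline(h = 0, lty = 3, col = "grey70")
  graphics::plot(p$time_ps, p$applied_force, type = "l", col = "grey60",
                 xlab = "time (ps)", ylab = "applied force (pN)", ...)
  if (nrow(p) >= 4) {
    graphics::lines(p$time_ps,
                    smooth_force_curve(p$applied_force, cutoff_pulses)$smoothed,
                    col = "blue", lwd = 2)
  }
  invisible(x)
}

#' Plot a velocity sweep (distance, velocity and force response)
#'
#' Three panels over the target-velocity grid: extension ratio r (the
#' distance response), mean pre-pulse velocity against the +/- v_target
#' guides, and maximum smoothed force against the theoretical cap
#' 2 M v_target. The estimated critical velocity is marked when
#' bracketed.
#'
#' @param x A \code{puff_sweep}.
#' @param ... Passed to \code{plot}.
#' @return \code{x}, invisibly.
#' @export
plot.puff_sweep <- function(x, ...) {
  s <- x$per_velocity
  old <- graphics::par(mfrow = c(3, 1), mar = c(4, 4.2, 1, 1))
  on.exit(graphics::par(old))
  graphics::plot(s$v_target, s$r, type = "b", ylim = c(0, max(1, s$r)),
                 xlab = "target velocity (A/ps)", ylab = "extension ratio r", ...)
  graphics::abline(h = c(0.1, 0.8), lty = 3, col = "grey70")
  graphics::plot(s$v_target, s$mean_pre_pulse_velocity, type = "b",
                 xlab = "target velocity (A/ps)",
                 ylab = "mean pre-pulse velocity (A/ps)", ...)
  graphics::lines(s$v_target, s$v_target, lty = 2, col = "grey40")
  graphics::lines(s$v_target, -s$v_target, lty = 2, col = "grey40")
  theo <- theoretical_max_force(x$pulling_mass_da, s$v_target)
  graphics::plot(s$v_target, s$max_smoothed_force, type = "b",
                 ylim = range(0, theo, s$max_smoothed_force),
                 xlab = "target velocity (A/ps)",
                 ylab = "max smoothed force (pN)", ...)
  graphics::lines(s$v_target, theo, col = "grey40")
  if (!is.na(x$v_critical)) {
    graphics::abline(v = x$v_critical, col = "red", lty = 2)
  }
  invisible(x)
}
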