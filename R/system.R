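#' Construct a bead-spring particle system
#'
#' The simulated state: masses, coordinates, velocities and a list of
#' bonded potential terms. This is the desk-scale stand-in for an
#' atomistic system; the pulling controller only ever touches it through
#' [compute_forces()], [nve_step()] and the anchor-group accessors, so the
#' same controller logic applies to restart states exchanged with a real
#' MD engine through [read_rst7()]/[write_rst7()].
#'
#' @param masses Length-N vector of masses, Da (strictly positive, N >= 2).
#' @param positions N x 3 matrix of coordinates, A.
#' @param velocities N x 3 matrix of velocities, A/ps (default zero).
#' @param bonds List of bond terms created by [bond_term()].
#' @param time Simulation clock, ps.
#' @return An object of class \code{particle_system}.
#' @export
particle_system <- function(masses, positions, velocities = NULL,
                            bonds = list(), time = 0) {
  masses <- as.numeric(masses)
  n <- length(masses)
  if (n < 2) stop("a particle system needs at least 2 particles", call. = FALSE)
  if (any(!is.finite(masses)) || any(masses <= 0)) {
    stop("masses must be finite and strictly positive", call. = FALSE)
  }
  positions <- as_velocity_matrix(positions)
  if (nrow(positions) != n) {
    stop("positions must have one row per particle", call. = FALSE)
  }
  if (is.null(velocities)) velocities <- matrix(0, n, 3)
  velocities <- as_velocity_matrix(velocities)
  if (nrow(velocities) != n) {
    stop("velocities must have one row per particle", call. = FALSE)
  }
  if (any(!is.finite(positions)) || any(!is.finite(velocities))) {
    stop("positions and velocities must be finite", call. = FALSE)
  }
  for (b in bonds) {
    if (!inherits(b, "bond_term")) stop("bonds must be bond_term objects", call. = FALSE)
    if (max(b$i, b$j) > n) stop("bond indexes a particle beyond n", call. = FALSE)
  }
  structure(
    list(masses = masses, positions = positions, velocities = velocities,
         bonds = bonds, time = as.numeric(time)),
    class = "particle_system"
  )
}

#' @export
print.particle_system <- function(x, ...) {
  n_broken <- sum(vapply(x$bonds, function(b) identical(b$intact, FALSE), logical(1)))
  cat(sprintf("<particle_system> %d beads, %d bonds (%d broken), t = %.4g ps\n",
              length(x$masses), length(x$bonds), n_broken, x$time))
  invisible(x)
}

#' Bonded potential term
#'
#' Three bond kinds are supported, each an analytic pair potential in the
#' bead separation r:
#' \describe{
#'   \item{harmonic}{V = k/2 (r - r0)^2; never ruptures (its restoring
#'     force is unbounded).}
#'   \item{morse}{V = D (1 - exp(-a (r - r0)))^2; the restoring force
#'     peaks at a*D/2 at the inflection point r0 + ln(2)/a.}
#'   \item{breakable}{harmonic up to an extension of \code{r_break}
#'     beyond r0, at which point the bond breaks irreversibly and exerts
#'     zero force for the rest of the run. Its rupture force is exactly
#'     k * r_break, which makes it the ground-truth fixture for
#'     parameter-recovery tests.}
#' }
#'
#' @param i,j 1-based particle indices (distinct).
#' @param kind One of \code{"harmonic"}, \code{"morse"}, \code{"breakable"}.
#' @param k Spring constant, Da/ps^2 (harmonic, breakable).
#' @param r0 Equilibrium length, A.
#' @param D Morse well depth, Da*A^2/ps^2.
#' @param a Morse width, 1/A.
#' @param r_break Rupture extension beyond r0, A (breakable).
#' @return An object of class \code{bond_term}.
#' @export
bond_term <- function(i, j, kind = c("harmonic", "morse", "breakable"),
                      k = NULL, r0 = NULL, D = NULL, a = NULL,
                      r_break = NULL) {
  kind <- match.arg(kind)
  i <- as.integer(i); j <- as.integer(j)
  if (i == j) stop("bond endpoints must differ", call. = FALSE)
  positive <- function(x, nm) {
    if (is.null(x) || !is.finite(x) || x <= 0) {
      stop(sprintf("bond parameter '%s' must be positive for kind '%s'", nm, kind),
           call. = FALSE)
    }
    as.numeric(x)
  }
  params <- switch(kind,
    harmonic  = list(k = positive(k, "k"), r0 = positive(r0, "r0")),
    morse     = list(D = positive(D, "D"), a = positive(a, "a"),
                     r0 = positive(r0, "r0")),
    breakable = list(k = positive(k, "k"), r0 = positive(r0, "r0"),
                     r_break = positive(r_break, "r_break"))
  )
  structure(
    c(list(i = i, j = j, kind = kind, intact = TRUE), params),
    class = "bond_term"
  )
}

#' Maximum restoring force of a bond (its rupture force)
#'
#' The analog of a protein's unfolding force for a single bonded term:
#' the maximum of |dV/dr| over r >= r0. Closed forms exist for morse
#' (a*D/2, at the inflection) and breakable (k*r_break, the force at the
#' instant of rupture); an unbreakable harmonic has no maximum and
#' returns \code{Inf}.
#'
#' @param bond A [bond_term()].
#' @param units \code{"pN"} (default) or \code{"internal"} (Da*A/ps^2).
#' @return Rupture force (scalar); \code{Inf} for an unbreakable harmonic.
#' @export
max_restoring_force <- function(bond, units = c("pN", "internal")) {
  units <- match.arg(units)
  stopifnot(inherits(bond, "bond_term"))
  f <- switch(bond$kind,
    harmonic  = Inf,
    morse     = bond$a * bond$D / 2,
    breakable = bond$k * bond$r_break
  )
  if (units == "pN" && is.finite(f)) f <- f * puff_constants()$force_per_da_accel
  f
}
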