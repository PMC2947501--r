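#' Internal unit system and physical constants
#'
#' All simulation state is kept in a single internal unit system:
#' angstrom (length), picosecond (time), dalton (mass), kelvin
#' (temperature). Forces are converted to piconewton only at the
#' analysis/reporting boundary. In these units one Da*A/ps^2 equals
#' 0.1660539 pN, and the Boltzmann constant is 0.8314463 Da*A^2/(ps^2*K).
#'
#' @return A list with components \code{force_per_da_accel} (pN per
#'   Da*A/ps^2) and \code{boltzmann} (Da*A^2/ps^2 per K).
#' @examples
#' puff_constants()$force_per_da_accel
#' @export
puff_constants <- function() {
  list(
    # 1 Da * 1 A/ps^2 = 1.66053907e-27 kg * 1e10 m / (1e-12 s)^2 * 1e12 (pN/N)
    force_per_da_accel = 0.1660539,
    # k_B = 1.380649e-23 J/K in Da*A^2/ps^2
    boltzmann = 0.8314463
  )
}

#' Convert a pulling mass from dalton to force-bookkeeping units
#'
#' The impulse bookkeeping F = M * dV mixes a mass in Da with a velocity
#' change in A/ps; expressing M in pN*ps^2/A makes the product come out
#' directly in pN. Anchor-group masses of a few hundred Da map to a few
#' tens of pN*ps^2/A (e.g. 262 Da -> 43.51, conventionally rounded to 44;
#' 206 Da -> 34.21 -> 34).
#'
#' @param mass_da Mass (or vector of masses) in Da. Must be non-negative.
#' @return Mass in pN*ps^2/A, full precision (callers round for display).
#' @seealso [theoretical_max_force()], [unfolding_force()]
#' @export
mass_to_force_units <- function(mass_da) {
  if (!is.numeric(mass_da) || any(!is.finite(mass_da))) {
    stop("'mass_da' must be finite numeric", call. = FALSE)
  }
  if (any(mass_da < 0)) {
    stop("'mass_da' must be non-negative", call. = FALSE)
  }
  mass_da * puff_constants()$force_per_da_accel
}

#' Instantaneous kinetic temperature of a velocity set
#'
#' Computes T = sum(m_i |v_i|^2) / (k_B * n_dof). With
#' \code{remove_com = TRUE} (the default used for thermostat targets) the
#' centre-of-mass translation is subtracted first and n_dof = 3N - 3, so
#' momentum injected by pulling impulses is not counted as heat. With
#' \code{remove_com = FALSE}, n_dof = 3N.
#'
#' @param velocities N x 3 matrix of velocities, A/ps.
#' @param masses Length-N vector of masses, Da (strictly positive).
#' @param remove_com Subtract the centre-of-mass velocity first?
#' @return Temperature in K.
#' @export
kinetic_temperature <- function(velocities, masses, remove_com = TRUE) {
  velocities <- as_velocity_matrix(velocities)
  n <- nrow(velocities)
  if (length(masses) != n) {
    stop("'masses' length must match number of velocity rows", call. = FALSE)
  }
  if (any(!is.finite(masses)) || any(masses <= 0)) {
    stop("'masses' must be finite and strictly positive", call. = FALSE)
  }
  if (remove_com) {
    if (n < 2) {
      stop("remove_com requires at least 2 particles (no internal dof left)",
           call. = FALSE)
    }
    vcom <- colSums(velocities * masses) / sum(masses)
    velocities <- sweep(velocities, 2, vcom, "-")
    n_dof <- 3 * n - 3
  } else {
    n_dof <- 3 * n
  }
  twice_ke <- sum(masses * rowSums(velocities^2))
  twice_ke / (puff_constants()$boltzmann * n_dof)
}

# Coerce a 3-vector or N x 3 matrix to an N x 3 matrix.
as_velocity_matrix <- function(v) {
  if (is.null(dim(v))) {
    if (length(v) %% 3L != 0L) {
      stop("velocity vector length must be a multiple of 3", call. = FALSE)
    }
    v <- matrix(v, ncol = 3, byrow = TRUE)
  }
  if (ncol(v) != 3) stop("velocities must have 3 columns", call. = FALSE)
  storage.mode(v) <- "double"
  v
}
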