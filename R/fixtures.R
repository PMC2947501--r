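#' Two-bead fixture system
#'
#' Two beads on the x-axis at a given separation, zero velocities. The
#' simplest system on which the pulling protocol is exercised: the two
#' beads are the two anchor groups, so the combined pulling mass is
#' \code{mass1 + mass2} (e.g. 112 + 112 = 224 Da, the scale of a pair of
#' terminal residues).
#'
#' @param mass1,mass2 Bead masses, Da.
#' @param bond Optional [bond_term()] joining beads 1 and 2 (indices are
#'   forced to 1 and 2), or \code{NULL} for a free pair.
#' @param separation Initial separation, A (> 0).
#' @return A [particle_system()].
#' @export
make_two_bead_system <- function(mass1, mass2, bond = NULL, separation = 4) {
  if (separation <= 0) stop("separation must be > 0", call. = FALSE)
  bonds <- list()
  if (!is.null(bond)) {
    stopifnot(inherits(bond, "bond_term"))
    bond$i <- 1L; bond$j <- 2L
    bonds <- list(bond)
  }
  particle_system(
    masses = c(mass1, mass2),
    positions = rbind(c(0, 0, 0), c(separation, 0, 0)),
    bonds = bonds
  )
}

#' Bead chain fixture (extended or hairpin geometry)
#'
#' Builds a chain with consecutive backbone bonds. The \code{"extended"}
#' geometry places beads along x at their bond rest lengths, so the
#' end-to-end distance equals the sum of the backbone r0 values (the
#' contour length). The \code{"hairpin"} geometry folds the chain into
#' two antiparallel strands joined by cross-links between opposing
#' beads; giving the cross-links staged rupture extensions produces a
#' two-stage rupture with a metastable, partially extended state in
#' between -- the generic analog of a mechanical unfolding intermediate.
#'
#' @param n_beads Number of beads (>= 3; even for hairpin).
#' @param masses Bead masses, Da (length 1 or n_beads).
#' @param bond_specs List of length n_beads - 1 of [bond_term()] objects
#'   for consecutive pairs (i, i+1); endpoint indices are overwritten.
#' @param geometry \code{"extended"} or \code{"hairpin"}.
#' @param cross_specs Hairpin only: list of cross-link bonds, each a
#'   [bond_term()] whose \code{i}, \code{j} name the opposing beads it
#'   ties (e.g. 1--n, 2--(n-1)).
#' @param strand_gap Hairpin inter-strand distance, A.
#' @return A [particle_system()].
#' @export
make_chain_system <- function(n_beads, masses, bond_specs,
                              geometry = c("extended", "hairpin"),
                              cross_specs = NULL, strand_gap = 2) {
  geometry <- match.arg(geometry)
  n_beads <- as.integer(n_beads)
  if (n_beads < 3) stop("a chain needs at least 3 beads", call. = FALSE)
  if (length(masses) == 1) masses <- rep(masses, n_beads)
  if (length(masses) != n_beads) {
    stop("masses must have length 1 or n_beads", call. = FALSE)
  }
  if (length(bond_specs) != n_beads - 1) {
    stop("bond_specs must have one bond per consecutive pair", call. = FALSE)
  }
  bonds <- vector("list", n_beads - 1)
  for (b in seq_len(n_beads - 1)) {
    bt <- bond_specs[[b]]
    stopifnot(inherits(bt, "bond_term"))
    bt$i <- b; bt$j <- b + 1L
    bonds[[b]] <- bt
  }
  r0s <- vapply(bonds, function(b) b$r0, numeric(1))

  if (geometry == "extended") {
    x <- c(0, cumsum(r0s))
    pos <- cbind(x, 0, 0)
  } else {
    if (n_beads %% 2L != 0L) stop("hairpin geometry needs an even bead count",
                                  call. = FALSE)
    half <- n_beads %/% 2L
    xa <- c(0, cumsum(r0s[seq_len(half - 1)]))
    # strand B runs back over strand A, offset by the strand gap
    pos <- rbind(cbind(xa, 0, 0), cbind(rev(xa), strand_gap, 0))
    if (!is.null(cross_specs)) {
      for (cs in cross_specs) {
        stopifnot(inherits(cs, "bond_term"))
        if (cs$i + cs$j != n_beads + 1L) {
          stop("hairpin cross-links must tie opposing beads (i + j = n + 1)",
               call. = FALSE)
        }
        bonds[[length(bonds) + 1]] <- cs
      }
    }
  }
  particle_system(masses = masses, positions = pos, bonds = bonds)
}

#' Named fixture library
#'
#' Ready-made synthetic systems with analytically known rupture forces,
#' used throughout the validation suite and available to the CLI by
#' name:
#' \describe{
#'   \item{free_pair}{Two free 112 Da beads at 50 A separation, no bond.
#'     The unimpeded-motion control: pulling it must give zero applied
#'     force after the first pulse and a separation slope equal to the
#'     target velocity.}
#'   \item{trapped_pair}{Two 112 Da beads (combined pulling mass 224 Da)
#'     joined by an unbreakable harmonic bond of stiffness 3584 Da/ps^2
#'     (relative-motion angular frequency 8 /ps) and rest length 4 A.
#'     Under pulling it reflects elastically off the potential wall
#'     every cycle: the pre-pulse velocity converges to exactly
#'     -v_target (the fixed point of the pulsed map) because a two-bead
#'     system has no internal modes to absorb the reflection.}
#'   \item{trapped_chain}{Four 112 Da beads joined by unbreakable
#'     harmonic bonds (k = 3584 Da/ps^2, r0 = 4 A), pulled between the
#'     end beads (pulling mass 224 Da). The two interior beads act as a
#'     small internal bath that partially absorbs each reflection, so
#'     the mean pre-pulse velocity is negative with magnitude below
#'     v_target -- the trapped-regime signature of a system with
#'     internal structure.}
#'   \item{breakable_pair}{Two equal beads joined by a breakable
#'     harmonic bond; see \code{mass} and \code{r_break} arguments. The
#'     stiffness default k = 32 m keeps the relative-motion frequency at
#'     8 /ps for every mass, so one pulse duration suits the whole
#'     rupture-force ladder (see [recovery_bond_set()]).}
#'   \item{hairpin}{Six-bead hairpin with two breakable cross-links of
#'     staged rupture force (outer weak, inner strong) and stiff
#'     unbreakable backbone; two-stage rupture with a partially extended
#'     metastable state at about 8 A separation and a 14 A contour.}
#' }
#'
#' @param name Fixture name.
#' @param mass Bead mass, Da (breakable_pair and hairpin only).
#' @param r_break Rupture extension, A (breakable_pair only).
#' @param k Override spring constant, Da/ps^2 (breakable_pair only).
#' @return List with components \code{system}, \code{anchors},
#'   \code{contour_length} (A or \code{NA}), \code{rupture_forces_pn}
#'   (sorted rupture forces of all breakable/morse bonds, pN) and
#'   \code{description}.
#' @export
puff_fixture <- function(name = c("free_pair", "trapped_pair", "trapped_chain",
                                  "breakable_pair", "hairpin"),
                         mass = 4000, r_break = 0.25, k = NULL) {
  name <- match.arg(name)
  fx <- switch(name,
    free_pair = list(
      system = make_two_bead_system(112, 112, separation = 50),
      anchors = anchor_spec(1, 2),
      contour_length = NA_real_,
      description = "two free beads, unimpeded-motion control"
    ),
    trapped_pair = {
      b <- bond_term(1, 2, "harmonic", k = 3584, r0 = 4)
      list(
        system = make_two_bead_system(112, 112, bond = b, separation = 4),
        anchors = anchor_spec(1, 2),
        contour_length = NA_real_,
        description = "unbreakable harmonic pair, trapped-regime reference"
      )
    },
    trapped_chain = {
      bs <- replicate(3, bond_term(1, 2, "harmonic", k = 3584, r0 = 4),
                      simplify = FALSE)
      list(
        system = make_chain_system(4, 112, bs, geometry = "extended"),
        anchors = anchor_spec(1, 4),
        contour_length = NA_real_,
        description = "unbreakable chain, trapped regime with internal bath"
      )
    },
    breakable_pair = {
      if (is.null(k)) k <- 32 * mass
      b <- bond_term(1, 2, "breakable", k = k, r0 = 4, r_break = r_break)
      list(
        # a severed pair extends without bound, so there is no contour
        # length and no saturated regime for this fixture
        system = make_two_bead_system(mass, mass, bond = b, separation = 4),
        anchors = anchor_spec(1, 2),
        contour_length = NA_real_,
        rupture_forces_pn = max_restoring_force(b),
        description = sprintf(
          "breakable pair, rupture force %.0f pN",
          max_restoring_force(b))
      )
    },
    hairpin = fixture_hairpin(mass = if (missing(mass)) 10000 else mass)
  )
  fx$name <- name
  fx
}

# Six-bead hairpin with staged cross-links. Bead mass m (default 10000
# Da, a domain-scale bead): the outer cross-link 1-6 (k = 32 m, r_break
# = 0.125 A) ruptures at one quarter the force of the inner 2-5 (k =
# 32 m, r_break = 0.5 A); the backbone (k = 24 m) never breaks, so the
# contour (14 A) bounds the extension. Stiffnesses keep every
# local vibration below ~10 /ps, so a reflection completes inside one
# 450 fs pulse and the 1 fs timestep integrates every mode cleanly.
fixture_hairpin <- function(mass = 10000) {
  kbb <- 24 * mass
  bb <- function(r0) bond_term(1, 2, "harmonic", k = kbb, r0 = r0)
  backbone <- list(bb(3), bb(3), bb(2), bb(3), bb(3))
  cross <- list(
    bond_term(1L, 6L, "breakable", k = 32 * mass, r0 = 2, r_break = 0.125),
    bond_term(2L, 5L, "breakable", k = 32 * mass, r0 = 2, r_break = 0.5)
  )
  sys <- make_chain_system(6, mass, backbone, geometry = "hairpin",
                           cross_specs = cross, strand_gap = 2)
  list(
    system = sys,
    anchors = anchor_spec(1, 6),
    contour_length = 14,
    rupture_forces_pn = sort(vapply(cross, max_restoring_force, numeric(1))),
    description = "six-bead hairpin, staged two-stage rupture"
  )
}

#' Rupture-force ladder for parameter-recovery runs
#'
#' Five breakable-pair fixtures whose rupture forces span a 10x range
#' (about 2000 to 21000 pN). Masses and rupture extensions are paired so
#' that (a) every bond keeps the same relative-motion frequency of 8 /ps
#' (k = 32 m), hence one pulse duration fits all, and (b) the energy
#' stored at rupture is at least ~13 k_B T at 300 K, so thermal
#' fluctuations cannot rupture a trapped bond over a full sweep.
#'
#' @return List of fixtures as returned by [puff_fixture()], each with
#'   an added \code{v_expected} (the target velocity at which the
#'   impulse bookkeeping 2 M v equals the bond's rupture force).
#' @export
recovery_bond_set <- function() {
  specs <- list(
    list(mass = 40000, r_break = 0.1000),
    list(mass = 12000, r_break = 0.1625),
    list(mass = 4200,  r_break = 0.2375),
    list(mass = 1700,  r_break = 0.3625),
    list(mass = 700,   r_break = 0.5500)
  )
  lapply(specs, function(s) {
    fx <- puff_fixture("breakable_pair", mass = s$mass, r_break = s$r_break)
    f_pn <- max_restoring_force(fx$system$bonds[[1]])
    m_pn <- mass_to_force_units(2 * s$mass)
    fx$v_expected <- f_pn / (2 * m_pn)
    fx
  })
}
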