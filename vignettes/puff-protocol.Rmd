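---
title: "Constant-momentum pulling: the protocol, its analysis, and the synthetic validation systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constant-momentum pulling: the protocol, its analysis, and the synthetic validation systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(puffmd)
```

## The protocol

Mechanical unfolding is probed computationally by pulling two anchor
groups of a molecule apart. Conventional steered MD does this with a
harmonic restraint whose target moves at constant velocity; the spring
keeps loading while the molecule resists, so the simulated peak forces
are dominated by spring elasticity and come out far above single-molecule
force-spectroscopy measurements. The PUFF (Pulsed Unconstrained
Fluctuating Forces) protocol implemented here replaces the spring with a
*constant-momentum* control: the run is cut into short pulses, and at
each pulse boundary the relative velocity of the two anchor groups along
their axis is reset instantaneously to a target value `v_target`. Between
resets the dynamics is unmodified.

One cycle of `run_puff()` does, in order:

1. record the separation and the **pre-pulse velocity** `V12,axis` (the
   relative axis velocity at the end of the previous relaxation — the raw
   dynamical response, sampled *before* the thermostat touches it);
2. rescale all velocities to the rescale temperature (default 300 K),
   removing the centre-of-mass velocity first;
3. apply the impulse: with `dV = v_target − V12,axis` and axis unit
   vector `N12` (group-1 COM toward group-2 COM), every atom of group 2
   gets `+0.5 dV N12` and every atom of group 1 gets `−0.5 dV N12`;
4. integrate at constant energy (velocity Verlet) for `pulse_fs`.

Because the reset is instantaneous, the momentum change is booked as the
applied force `F = M dV`, with `M` the combined mass of both anchor
groups expressed in pN ps²/Å (`mass_to_force_units()`; 1 Da Å/ps² =
0.1660539 pN). The reset can only change the velocity by at most
`2 v_target` once the system reflects fully, so the applied force is
capped at

```
F_max = 2 M v_target        (theoretical_max_force)
```

and the smallest target velocity at which unfolding proceeds unimpeded —
the critical velocity — converts into an unfolding-force estimate
`F_unfold = 2 M v_critical` (`unfolding_force()`, reported rounded to
the nearest pN, e.g. 2 × 44 × 1.8 = 158 pN).

Two points in the cycle were genuinely open and are fixed here as
package policy:

* **Rescale-then-impulse ordering.** The thermostat acts first so that it
  never distorts the freshly reset velocity; the pre-pulse velocity is
  sampled before both. Anchor atoms are included in the rescale.
* **Equal accelerations, not equal impulses.** The ±0.5 dV scheme changes
  net system momentum when the two groups have unequal mass. This is the
  reference behaviour; `puff_params(remove_com_drift = TRUE)` subtracts
  the injected drift after each impulse for users who want strict
  momentum conservation.
* `F = M dV` uses the *combined* anchor mass with the *full* dV even
  though each group receives half of it; the printed worked examples
  (82 pN at M = 41 pN ps²/Å, v = 1 Å/ps) are consistent only with that
  bookkeeping, so it is what the package implements.

A `v_target` of 0 is allowed: the protocol degenerates into a velocity
clamp that actively damps spontaneous separation fluctuations — useful
for holding a state in place.

## The toy engine

The built-in engine is a bead–spring model: point beads (Da), three bond
kinds (harmonic; Morse; breakable-harmonic, which snaps irreversibly when
its extension exceeds `r_break`), velocity-Verlet NVE segments, and BAOAB
Langevin equilibration with friction γ in ps⁻¹. A printed friction of
"5 s⁻¹" would be physically inert on picosecond timescales; the package
follows the conventional MD input unit and uses γ = 5 ps⁻¹. Everything is
kept in Å / ps / Da / K internally; forces become pN only at the
reporting boundary, which avoids double conversions.

`max_restoring_force()` gives each bond's exact rupture force —
`k r_break` for a breakable bond, `a D / 2` for Morse at its inflection,
unbounded (`Inf`) for a plain harmonic bond — which is what makes the
synthetic systems useful: the quantity the sweep analysis estimates is
known in closed form.

Restart-file interop (`read_rst7()` / `write_rst7()`) uses the classic
fixed-width ASCII dialect so the same controller logic can drive an
external engine; restart velocities are in Å per 1/20.455 ps and
`convert_velocity_units()` applies that factor only at the file boundary.

## Why the fixtures look the way they do

The fixtures are not arbitrary: each one is placed, by construction, in
the dynamical regime the corresponding analysis assumes.

**Reflection must complete within one pulse.** The unfolding-force
estimate `2 M v_critical` equates the per-pulse momentum ration with the
barrier force. For a bonded pair of reduced mass μ and well frequency
ω = √(k/μ), the true rupture condition is reached when the reflection
amplitude `v/ω` exceeds `r_break`, i.e. at `v_crit = ω r_break`, so
`2 M v_crit ≈ F_rupture` requires `ω μ ≈ 2M` *and* a pulse long enough
(`ω T ≳ π`) for the reflection to finish before the next reset. With
equal bead masses this fixes `k = 32 m` (ω = 8 ps⁻¹ for every mass) and a
450 fs pulse (ωT ≈ 3.6). This is the package's concrete instance of the
general statement that the relaxation time must let the system explore
its local well: too-short pulses never let the system push back, while
much longer pulses let it drift.

**Thermal sharpness.** A breakable bond must not rupture by thermal
fluctuation while trapped, over a whole sweep: the ladder of five
recovery bonds (`recovery_bond_set()`, rupture forces ~2000–21000 pN,
a > 10× span) stores at least ~13 k_BT at the rupture extension. Rungs
are (mass, r_break) pairs; the v ≈ grid resolution 0.2 Å/ps limits how
low a critical velocity can be measured accurately, which bounds the
ladder from below.

**Repeat starts.** Sweeps cycle over five starting conformations
snapshotted from the tail of the equilibration. With a single shared
start, one atypical draw (a bond stretched by ~2.5 σ at the moment the
equilibration ends) biases *every* velocity of the sweep coherently and
can fake a contiguous constant-momentum block well below the true
boundary; with cycled starts the damage is an isolated label that cannot
move the boundary estimate.

**Trapped-regime fixtures.** A two-bead harmonic pair
(`puff_fixture("trapped_pair")`) reflects elastically, and the pulse map
on the bond coordinate is deterministic (the rescale touches only
velocities, and the impulse overwrites the bond velocity): its fixed
point gives a pre-pulse velocity of exactly −v_target, which the unit
tests assert. A real molecule shows *partial* reflection (pre-pulse
magnitudes below v_target) because internal degrees of freedom absorb
part of each reflection. The smallest system that reproduces this is a
short chain: `puff_fixture("trapped_chain")` (four 112-Da beads, anchor
mass 224 Da) yields pooled mean pre-pulse velocities around −0.5 to −0.9
Å/ps at v_target = 1 — the partial-reflection band — while its applied
force rides within ~10 % of the 2 M v cap. Because the two interior
beads are a very small bath, the signature is measured over 200-pulse
runs pooled across the five repeat starts; in much longer runs the bath
saturates and the mean drifts back toward −v_target, which is a finite-
size effect, not a protocol property.

**Staged hairpin.** `puff_fixture("hairpin")` folds six beads into two
strands tied by two breakable cross-links, the outer one four times
weaker than the inner. Pulling with a force cap between the two rupture
forces breaks only the outer link and leaves the system dwelling at
~8 Å separation — a clean, geometry-level analog of an unfolding
intermediate, detected by `detect_plateaus()`. Below the weak link the
system stays folded; far above the strong link it extends to its 14 Å
contour with no intermediate dwell. The backbone never breaks, which is
what gives the fixture a genuine contour length and a saturated regime.

All bond stiffnesses in the library keep local vibration frequencies
below ~12 ps⁻¹, so the 1 fs production timestep integrates every fixture
with pulse-interior energy drift below 1e-5 (relative); the drift
property is tested across the library at exactly that timestep.

## Response analysis

* `smooth_force_curve()` low-pass filters the per-pulse force series in
  the Fourier domain, zeroing components with period below
  `cutoff_pulses` (default 20). The default is chosen so that the slow
  envelope of a 100-plus-pulse trace survives while per-pulse fluctuation
  (which is of order the cap itself) is removed. DC is always kept, so a
  constant series is unchanged.
* `classify_regime()` reduces a trajectory to the extension ratio
  `r = (final − initial separation) / (v_target × time)` and labels it
  trapped (r < 0.1), intermittent (0.1 ≤ r < 0.8), constant-momentum
  (r ≥ 0.8), or saturated (95 % of the contour length reached before the
  last 10 % of the run). The 0.1/0.8/0.95 cutoffs are package defaults
  chosen to reproduce the four-band structure cleanly on the fixture
  systems; they are exposed in the regime functions rather than
  hard-wired into the sweep driver. Fixtures without a meaningful
  contour (a severed pair extends without bound) use `contour_length =
  NA`, which disables the saturation test.
* `estimate_critical_velocity()` reports the smallest grid velocity
  labelled constant-momentum such that every larger, non-saturated
  velocity is too. It reports at grid resolution (no interpolation),
  errors when the grid never reaches the constant-momentum range, and
  warns when the whole grid is already past the boundary.
* `detect_plateaus()` finds maximal intervals during which the
  separation stays within `tolerance_A` (default 2 Å) of the interval
  mean for at least `min_duration_ps` (default 20 % of the run), then
  merges adjacent intervals separated by less than the minimum duration
  whose means differ by less than the tolerance — a slowly creeping
  metastable level is one plateau, not several. Plateaus are classified
  folded / intermediate / unfolded by extension relative to the initial
  separation and the contour length.
* `mean_pre_pulse_velocity()` discards a burn-in (default 10 % of
  pulses) because the early response reflects the start-up transient.

## Problem sizes and determinism

The shipped validation runs are desk-scale by design: equilibrations of
10–20 ps, pulling runs of 30–200 pulses (3–90 ps of dynamics), sweeps of
6–34 grid points on two- to six-bead systems. The full test suite
simulates a few million integrator steps in under two minutes. The pulse
loop itself is deterministic — randomness enters only through the seeded
Langevin equilibration — so fixed seeds give bit-identical pulse logs,
which the suite asserts.

## What the synthetic systems do and do not show

The bead–spring fixtures exercise every moving part of the protocol and
analysis against ground truth that real systems cannot provide: exact
rupture forces, exact ballistic limits, exact reflection fixed points.
Passing them shows the controller applies the impulses it claims, caps
forces where the theory says, recovers known rupture forces within the
method's own ~30 % accuracy scale, and resolves staged ruptures into
intermediates. It does *not* show anything about force fields, solvent,
hydrogen-bond-level unfolding pathways, or the kinetics of unfolding at
fixed velocity — the protocol does not model velocity-dependent rates,
and atomistic work (the regime the printed 82/213/158/109 pN worked
examples come from) requires a real MD engine, which this package can
feed through its restart-file boundary but does not replace.

## Known limitations

* The pairwise bead model has no angles, dihedrals or excluded volume; a
  "contour length" is meaningful only where unbreakable backbone bonds
  provide one.
* The rescale thermostat is the crude velocity-rescale of the original
  workflow, kept deliberately; it is not a canonical-ensemble thermostat.
* With unequal anchor-group masses the uncorrected protocol injects net
  momentum (see above); long runs with very asymmetric anchors should
  enable the drift correction.
* Critical velocities are grid-resolution quantities; the recovered
  unfolding force inherits that quantisation (±0.2 Å/ps ≈ ±7 % at
  v_critical ≈ 3 Å/ps).
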