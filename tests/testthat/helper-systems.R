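# Shared fixture builders for the test suite. Everything is generated
# in code; no stored data files.

# n-bead chain of equal harmonic bonds along x
chain_system <- function(n = 4, k = 3584, r0 = 4, mass = 112) {
  bonds <- replicate(n - 1, bond_term(1, 2, "harmonic", k = k, r0 = r0),
                     simplify = FALSE)
  make_chain_system(n, mass, bonds, geometry = "extended")
}

# random bonded chain with mixed bond kinds, for gradient/property tests
random_chain <- function(seed, n = 6) {
  set.seed(seed)
  kinds <- sample(c("harmonic", "morse", "breakable"), n - 1, replace = TRUE)
  bonds <- lapply(seq_len(n - 1), function(i) {
    switch(kinds[i],
      harmonic  = bond_term(i, i + 1, "harmonic",
                            k = runif(1, 500, 5000), r0 = runif(1, 2, 5)),
      morse     = bond_term(i, i + 1, "morse", D = runif(1, 500, 3000),
                            a = runif(1, 0.5, 1.5), r0 = runif(1, 2, 5)),
      breakable = bond_term(i, i + 1, "breakable",
                            k = runif(1, 500, 5000), r0 = runif(1, 2, 5),
                            r_break = runif(1, 1, 3))
    )
  })
  pos <- cbind(cumsum(runif(n, 2, 5)), runif(n, -0.5, 0.5), runif(n, -0.5, 0.5))
  particle_system(
    masses = runif(n, 50, 500), positions = pos,
    velocities = matrix(rnorm(3 * n), n, 3), bonds = bonds
  )
}

# cold two-bead free pair moving apart along x at relative velocity v
cold_free_pair <- function() {
  make_two_bead_system(112, 112, bond = NULL, separation = 50)
}

# fabricate a minimal trajectory object from a separation/velocity series
fake_trajectory <- function(separation,
                            pre_pulse_velocity = rep(0, length(separation)),
                            applied_force = rep(0, length(separation)),
                            v_target = 1, pulse_fs = 100) {
  n <- length(separation)
  t <- (seq_len(n) - 1) * pulse_fs * 1e-3
  structure(
    list(
      params = puff_params(v_target = v_target, pulse_fs = pulse_fs,
                           n_pulses = n),
      anchors = anchor_spec(1, 2),
      pulses = data.frame(index = seq_len(n), time_ps = t,
                          separation = separation,
                          pre_pulse_velocity = pre_pulse_velocity,
                          delta_v = v_target - pre_pulse_velocity,
                          applied_force = applied_force,
                          axis_x = 1, axis_y = 0, axis_z = 0),
      snapshots = list(), final_system = NULL,
      pulling_mass_da = 224, error = NULL
    ),
    class = "puff_trajectory"
  )
}
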