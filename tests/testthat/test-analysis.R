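test_that("separation slope fitting recovers known slopes", {
  t6 <- fake_trajectory(separation = 10 + 6.0 * (0:49) * 0.1)
  expect_equal(fit_separation_slope(t6), 6.0, tolerance = 1e-9)
  tc <- fake_trajectory(separation = rep(50, 40))
  expect_equal(fit_separation_slope(tc), 0, tolerance = 1e-12)
  # window restriction
  sep <- c(rep(10, 20), 10 + 2 * (1:20) * 0.1)
  tw <- fake_trajectory(separation = sep)
  expect_equal(fit_separation_slope(tw, window = c(2.0, 3.9)), 2,
               tolerance = 1e-6)
  expect_error(fit_separation_slope(fake_trajectory(c(1, 2))),
               "insufficient")
})

test_that("low-pass FFT filter keeps the envelope and removes fast fluctuation", {
  # DC preservation
  const <- rep(80, 64)
  sm <- smooth_force_curve(const, cutoff_pulses = 20)
  expect_equal(sm$smoothed, const)
  expect_equal(sm$max, 80)
  # a pure fast oscillation (period 4 pulses) vanishes below a cutoff of 20
  fast <- sin(2 * pi * (0:127) / 4)
  expect_lt(max(abs(smooth_force_curve(fast, 20)$smoothed)), 1e-10)
  # slow ramp + fast noise: smoothed max near the noiseless envelope max
  set.seed(3)
  n <- 200
  envelope <- 100 * exp(-((0:(n - 1)) - 60)^2 / (2 * 30^2))
  noisy <- envelope + rnorm(n, sd = 15) + 40 * sin(2 * pi * (0:(n - 1)) / 3)
  sm2 <- smooth_force_curve(noisy, cutoff_pulses = 20)
  expect_equal(sm2$max, max(envelope), tolerance = 0.10)
  expect_error(smooth_force_curve(rep(1, 3)), "at least 4")
  expect_error(smooth_force_curve(const, cutoff_pulses = 1), "invalid cutoff",
               ignore.case = TRUE)
})

test_that("smoothing realistic pulse-force traces never raises the maximum", {
  set.seed(9)
  for (rep in 1:10) {
    n <- sample(50:300, 1)
    base <- cumsum(rnorm(n, sd = 2))
    base <- base - min(base)
    noisy <- base + rnorm(n, sd = 10)
    sm <- smooth_force_curve(noisy, cutoff_pulses = sample(5:40, 1))
    expect_lte(sm$max, max(noisy) + 1e-9)
  }
})

test_that("mean pre-pulse velocity averages after burn-in", {
  alt <- fake_trajectory(separation = rep(10, 60),
                         pre_pulse_velocity = rep(c(2, -2), 30))
  expect_equal(mean_pre_pulse_velocity(alt, burn_in_pulses = 0), 0)
  ramp <- fake_trajectory(separation = rep(10, 50),
                          pre_pulse_velocity = c(rep(9, 5), rep(1, 45)))
  expect_equal(mean_pre_pulse_velocity(ramp, burn_in_pulses = 5), 1)
  expect_error(mean_pre_pulse_velocity(ramp, burn_in_pulses = 50),
               "insufficient")
})

test_that("regime classification follows the extension ratio and saturation rule", {
  n <- 100
  # separation frozen at its initial value: trapped
  tr <- fake_trajectory(separation = rep(50, n), v_target = 1)
  expect_equal(classify_regime(tr, 1, contour_length = 300)$regime, "trapped")
  expect_lt(classify_regime(tr, 1, contour_length = 300)$r, 0.01)
  # moving at the target rate, below the contour: constant momentum
  cm <- fake_trajectory(separation = 50 + 1 * (0:(n - 1)) * 0.1, v_target = 1)
  cls <- classify_regime(cm, 1, contour_length = 300)
  expect_equal(cls$regime, "constant_momentum")
  expect_equal(cls$r, 1, tolerance = 0.05)
  # half the rate: intermittent
  im <- fake_trajectory(separation = 50 + 0.4 * (0:(n - 1)) * 0.1, v_target = 1)
  expect_equal(classify_regime(im, 1, contour_length = 300)$regime,
               "intermittent")
  # hitting 95% of the contour early: saturated
  sat_sep <- pmin(50 + 8 * (0:(n - 1)) * 0.1, 60)
  sat <- fake_trajectory(separation = sat_sep, v_target = 8)
  expect_equal(classify_regime(sat, 8, contour_length = 60)$regime,
               "saturated")
  # v_target = 0 is trapped by convention
  expect_equal(classify_regime(tr, 0, contour_length = 300)$regime, "trapped")
})

test_that("critical velocity is the lower edge of the constant-momentum range", {
  sweep <- data.frame(
    v_target = 1:5,
    regime = c("trapped", "trapped", "intermittent", "constant_momentum",
               "constant_momentum"))
  expect_equal(estimate_critical_velocity(sweep), 4)
  # a relapse below the boundary moves the estimate up
  sweep2 <- data.frame(
    v_target = 1:5,
    regime = c("trapped", "constant_momentum", "intermittent",
               "constant_momentum", "constant_momentum"))
  expect_equal(estimate_critical_velocity(sweep2), 4)
  # saturated points are ignored when checking "all larger velocities"
  sweep3 <- data.frame(
    v_target = 1:5,
    regime = c("trapped", "intermittent", "constant_momentum",
               "constant_momentum", "saturated"))
  expect_equal(estimate_critical_velocity(sweep3), 3)
  all_cm <- data.frame(v_target = 1:3, regime = rep("constant_momentum", 3))
  expect_warning(v <- estimate_critical_velocity(all_cm), "unresolved")
  expect_equal(v, 1)
  none <- data.frame(v_target = 1:3, regime = rep("trapped", 3))
  expect_error(estimate_critical_velocity(none), "not bracketed")
})

test_that("unfolding force units and rounding behave", {
  expect_equal(unfolding_force(44, 1.8), 158)
  expect_equal(unfolding_force(224, 2.6, mass_units = "Da"),
               round(2 * mass_to_force_units(224) * 2.6))
  expect_error(unfolding_force(0, 1), "positive")
})

test_that("plateau detection finds, merges and classifies levels", {
  n <- 200
  # constant separation: one folded plateau spanning the run
  flat <- fake_trajectory(separation = rep(30, n))
  rep1 <- detect_plateaus(flat, min_duration_ps = 2, tolerance_A = 2)
  expect_equal(nrow(rep1), 1)
  expect_equal(rep1$classification, "folded")
  expect_equal(rep1$start_ps, 0)
  # monotonic growth: no plateau at all
  mono <- fake_trajectory(separation = 10 + (0:(n - 1)) * 0.2)
  expect_equal(nrow(detect_plateaus(mono, min_duration_ps = 2,
                                    tolerance_A = 1)), 0)
  # two-level staircase: folded then intermediate then unfolded
  sep <- c(rep(10, 70), seq(10, 20, length.out = 10), rep(20, 60),
           seq(20, 40, length.out = 10), rep(40, 50))
  st <- fake_trajectory(separation = sep)
  rep2 <- detect_plateaus(st, min_duration_ps = 3, tolerance_A = 2,
                          contour_length = 40)
  expect_equal(rep2$classification, c("folded", "intermediate", "unfolded"))
  # a brief excursion inside one level is merged away
  sep3 <- rep(20, n); sep3[100] <- 26
  ex <- fake_trajectory(separation = sep3)
  rep3 <- detect_plateaus(ex, min_duration_ps = 2, tolerance_A = 2)
  expect_equal(nrow(rep3), 1)
  expect_error(detect_plateaus(flat, min_duration_ps = 100), "shorter")
})

test_that("a small sweep recovers the rupture force of one breakable bond", {
  fx <- puff_fixture("breakable_pair", mass = 4200, r_break = 0.2375)
  f_true <- max_restoring_force(fx$system$bonds[[1]])
  eq <- langevin_equilibrate(fx$system, 300, duration_ps = 10, seed = 13)
  sweep <- run_velocity_sweep(eq$system, fx$anchors,
                              v_grid = seq(0.6, 3.0, by = 0.4),
                              contour_length = NA, pulse_fs = 450,
                              n_pulses = 30, seed = 13)
  expect_false(is.na(sweep$v_critical))
  f_rec <- 2 * mass_to_force_units(sweep$pulling_mass_da) * sweep$v_critical
  expect_lt(abs(f_rec - f_true) / f_true, 0.3)
  # regime monotonicity: once constant momentum, never back to trapped
  reg <- sweep$per_velocity$regime[order(sweep$per_velocity$v_target)]
  reg <- reg[reg != "saturated"]
  first_cm <- match("constant_momentum", reg)
  expect_false(any(reg[first_cm:length(reg)] == "trapped"))
  # force-response deviation point agrees with the regime boundary
  frc <- force_response_curve(sweep)
  expect_lte(abs(frc$deviation_velocity - sweep$v_critical), 0.4 + 1e-9)
  # below the critical velocity the system resists at full strength
  below <- sweep$per_velocity$v_target < sweep$v_critical - 0.4
  if (any(below)) {
    theo <- theoretical_max_force(sweep$pulling_mass_da,
                                  sweep$per_velocity$v_target[below])
    expect_true(all(sweep$per_velocity$max_smoothed_force[below] >
                      0.7 * theo))
  }
})
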