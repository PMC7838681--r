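# Expected values are direct arithmetic evaluations of the model equations
# with the default (published) constants, written out literally.

test_that("respiratory signal is the sine of the phase", {
  expect_identical(respiratory_signal(0), 0)
  expect_equal(respiratory_signal(pi / 2), 1)
  expect_equal(respiratory_signal(2 * pi * 1.0 / 3.57), sin(1.76), tolerance = 1e-4)
  expect_true(all(abs(respiratory_signal(seq(-10, 10, by = 0.1))) <= 1))
})

test_that("cardiac contractility saturates towards the resting ceiling", {
  # S' = s_hat = 40 is the fixed point of the saturation map
  l_fix <- (40 + 13.8) / 45
  expect_equal(cardiac_contractility(0, 0, l_fix, tab_params), 40)
  # direct evaluation: S' = -13.8 + 10*2 + 20*1 + 45*1 = 71.2
  sprime <- 71.2
  s_expected <- sprime + (40 - sprime) * sprime^2.5 / (40^2.5 + sprime^2.5)
  expect_equal(cardiac_contractility(2, 1, 1, tab_params), s_expected)
  expect_equal(s_expected, 45.97, tolerance = 1e-3)
  # S' = 0 returns 0 (saturation skipped)
  expect_equal(cardiac_contractility(0, 0, 13.8 / 45, tab_params), 0)
  expect_error(cardiac_contractility(0, 0, -1, tab_params))
})

test_that("systolic pulse launches from D and peaks at D + S (peaked form)", {
  expect_equal(systolic_pressure(0, 75, 36, 0, tab_params), 75)
  expect_equal(systolic_pressure(0.125, 75, 36, 0, tab_params), 111)
  expect_equal(systolic_pressure(0.125, 75, 36, 0, tab_params, form = "literal"),
               75 + 36 * exp(1))
  # respiration rides on top
  expect_equal(systolic_pressure(0.125, 75, 36, 1, tab_params), 111 + 4)
  expect_error(systolic_pressure(0.2, 75, 36, 0, tab_params))
  expect_error(systolic_pressure(-0.01, 75, 36, 0, tab_params))
})

test_that("Windkessel time constant and diastolic decay follow the closed form", {
  expect_equal(peripheral_resistance_time_constant(0, tab_params), 2.0)
  expect_equal(peripheral_resistance_time_constant(1, tab_params), 2 * (1 + 1.2))
  expect_equal(peripheral_resistance_time_constant(5, cvs_parameters(k_Rv = 0)), 2.0)
  expect_error(peripheral_resistance_time_constant(-1, tab_params))
  expect_identical(diastolic_derivative(0, 0, tab_params), 0)
  expect_equal(diastolic_derivative(88, 0, tab_params), -44)
})

test_that("baroreceptor activity is linear in pressure and its derivative", {
  expect_equal(baroreceptor_activity(50, 0, tab_params), 0)
  expect_equal(baroreceptor_activity(110, 0, tab_params), 3)
  expect_equal(baroreceptor_activity(110, 100, tab_params), 3.1)
  expect_equal(baroreceptor_activity(110, 100, tab_params, node = "lower_body"), 3.1)
  # negative below threshold, not clipped
  expect_lt(baroreceptor_activity(40, 0, tab_params), 0)
})

test_that("sympathetic activity follows the sigmoid in both conventions", {
  # printed form at rest: -tanh(-4) - 0.25
  expect_equal(sympathetic_activity(0, 0, awake, tab_params, form = "printed"),
               -tanh(-4) - 0.25, tolerance = 1e-12)
  expect_equal(sympathetic_activity(0, 0, awake, tab_params, form = "printed"),
               0.7493, tolerance = 1e-4)
  # zero sigmoid argument leaves only the offset y_s
  expect_equal(sympathetic_activity(4 / 0.44, 0, awake, tab_params, form = "printed"),
               -0.25, tolerance = 1e-12)
  expect_equal(sympathetic_activity(4, 0, awake, tab_params, form = "centered"),
               -0.25, tolerance = 1e-12)
  # vessel loop shares the awake constants
  expect_equal(sympathetic_activity(2, 0.5, awake, tab_params, loop = "vessel"),
               sympathetic_activity(2, 0.5, awake, tab_params, loop = "heart"))
  # bounds: |v_s - y_s - k_sr*B| <= |a_s| for any input
  for (vb in seq(-5, 15, by = 0.5)) {
    for (B in c(-1, 0, 1)) {
      v <- sympathetic_activity(vb, B, awake, tab_params)
      expect_lte(abs(v - (-0.25) - 0.1 * B), 1)
    }
  }
})

test_that("parasympathetic activity is floored at zero", {
  expect_equal(parasympathetic_activity(0, 0, awake, tab_params), 0)  # max(0, -0.5)
  expect_equal(parasympathetic_activity(3, 0, awake, tab_params), -0.5 + 0.44 * 3)
  expect_equal(parasympathetic_activity(3, 0, nrem, tab_params),
               0.6 - 0.5 + (-0.19 + 0.44) * 3)
  grid <- expand.grid(vb = seq(-10, 10, by = 1), B = seq(-1, 1, by = 0.5))
  expect_true(all(parasympathetic_activity(grid$vb, grid$B, awake, tab_params) >= 0))
})

test_that("noradrenaline kinetics have the closed-form steady states", {
  expect_identical(noradrenaline_derivative(0, 0, tab_params), 0)
  # dc/dt = 0 at c* = tau_c * k_cS * v_s
  expect_equal(noradrenaline_derivative(2 * 0.04 * 1, 1, tab_params), 0)
  expect_equal(2 * 0.04 * 1, 0.08)
  # vascular: c* = tau_v * k_vS * (v_sl + k_v)
  cstar <- 2 * 0.52 * (0.8 + 0.2)
  expect_equal(cstar, 1.04)
  expect_equal(noradrenaline_derivative(cstar, 0.8, tab_params,
                                        compartment = "vascular"), 0)
})

test_that("autonomic factors equal one at zero drive", {
  expect_identical(sympathetic_factor(0, awake, tab_params), 1)
  # correction term vanishes at c_c = c_hat_c
  expect_equal(sympathetic_factor(2, awake, tab_params), 1 + 3.7 * 2)
  expect_equal(sympathetic_factor(0.1, awake, tab_params),
               1 + 3.7 * (0.1 + (2 - 0.1) * 0.01 / (4 + 0.01)))
  expect_identical(parasympathetic_factor(0, 0.8, awake, tab_params), 1)
  expect_equal(parasympathetic_factor(1, 0.45, awake, tab_params), 1)  # F(0.45)=0
  f08 <- 0.8^1.3 * (0.8 - 0.45) * 0.2^3 / (0.008 + 0.2^3)
  expect_equal(parasympathetic_factor(1, 0.8, awake, tab_params),
               1 + 3.75 * (1 + (2.5 - 1) * 1 / (2.5^2 + 1)) * f08)
  expect_error(parasympathetic_factor(-0.5, 0.5, awake, tab_params))
})

test_that("phase effectiveness has roots only at 0, 0.45 and 1", {
  expect_equal(phase_effectiveness(c(0, 0.45, 1)), c(0, 0, 0))
  phis <- seq(0.01, 0.99, by = 0.01)
  f <- phase_effectiveness(phis)
  expect_true(all(f[phis < 0.45] < 0))
  expect_true(all(f[phis > 0.45 & phis < 1] > 0))
  expect_equal(phase_effectiveness(0.8), 0.8^1.3 * 0.35 * 0.5)
  expect_error(phase_effectiveness(1.2))
  expect_error(phase_effectiveness(-0.1))
})

test_that("phase derivative is the modulated intrinsic rate", {
  expect_equal(phase_derivative(0, 1, 1, tab_params), 1 / 1.1)
  expect_equal(phase_derivative(0, 2, 1, tab_params),
               2 * phase_derivative(0, 1, 1, tab_params))
  expect_equal(phase_derivative(0.1, 1, 1, tab_params), 1 / 1.2)
  expect_error(phase_derivative(-1.1, 1, 1, tab_params))
})

test_that("presets match the published stage columns", {
  expect_true(all(unlist(awake) == 0))
  expect_equal(rem$c_sv, -0.1)
  expect_equal(rem$c_phip, -0.15)
  expect_equal(nrem$c_sv, -0.5)
  expect_equal(nrem$c_pv, 0.6)
  expect_error(sleep_preset("n3"))
  expect_error(cvs_parameters(nonsense = 1))
  expect_error(cvs_parameters(t_sys = 2))  # t_sys must stay below t0
})
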