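test_that("denervated, noise-free node fires at exactly the intrinsic period", {
  sim <- simulate_cvs("awake", duration = 80, transient = 10, noise = FALSE,
                      denervated = TRUE)
  ib <- ibi_series(sim)$ibi
  expect_gt(length(ib), 50)
  expect_lt(max(abs(ib - 1.1)), 1e-6)
})

test_that("simulations are deterministic given a seed", {
  a <- simulate_cvs("awake", duration = 160, transient = 100, seed = 4)
  b <- simulate_cvs("awake", duration = 160, transient = 100, seed = 4)
  expect_identical(a$beat_times, b$beat_times)
  expect_identical(a$sp, b$sp)
  # with noise off the seed is irrelevant
  c1 <- simulate_cvs("awake", duration = 160, transient = 100, seed = 1, noise = FALSE)
  c2 <- simulate_cvs("awake", duration = 160, transient = 100, seed = 2, noise = FALSE)
  expect_identical(c1$beat_times, c2$beat_times)
})

test_that("halving the step changes the post-transient mean IBI by < 0.1%", {
  m <- vapply(c(0.001, 0.0005), function(h) {
    mean(ibi_series(simulate_cvs("awake", duration = 400, transient = 240,
                                 noise = FALSE, dt = h))$ibi)
  }, numeric(1))
  expect_lt(abs(m[1] - m[2]) / m[1], 0.001)
})

test_that("post-transient pressure and interbeat intervals stay physiological", {
  for (st in c("awake", "rem", "nrem")) {
    for (sd in 1:3) {
      sim <- simulate_cvs(st, duration = 360, transient = 120, seed = sd)
      keep <- sim$beat_times > 120
      expect_gt(min(sim$dp[keep]), 20)
      expect_lt(max(sim$sp[keep]), 250)
      ib <- ibi_series(sim)$ibi
      expect_gt(min(ib), 0.3)
      expect_lt(max(ib), 3)
      expect_true(all(ib > 0))
    }
  }
})

test_that("diastolic decay matches the Windkessel closed form", {
  # k_vS = 0 keeps c_v identically zero, so R*C = r0c = 2 s exactly
  sim <- simulate_cvs("awake", duration = 100, transient = 30, noise = FALSE,
                      params = cvs_parameters(k_vS = 0),
                      keep_traces = TRUE)
  tr <- sim$trace
  expect_lt(max(abs(tr$c_v)), 1e-12)
  bt <- sim$beat_times[sim$beat_times > 30]
  worst <- 0
  for (i in 1:10) {
    t0 <- bt[i] + 0.15            # safely inside diastole
    t1 <- bt[i + 1] - 0.01
    seg <- tr[tr$t >= t0 & tr$t <= t1, ]
    pred <- seg$p[1] * exp(-(seg$t - seg$t[1]) / 2.0)
    worst <- max(worst, max(abs(seg$p - pred) / pred))
  }
  expect_lt(worst, 1e-4)
})

test_that("noradrenaline relaxes to its closed-form steady state under constant drive", {
  # no baroreflex (k1 = 0) and no respiratory coupling: v_s and v_sl are the
  # constant resting activities, so c_c -> tau_c k_cS v_s etc.
  pars <- cvs_parameters(k1 = 0, k1l = 0, k2 = 0, k2l = 0, k_sr = 0, k_slr = 0)
  sim <- simulate_cvs("awake", duration = 90, transient = 0, noise = FALSE,
                      params = pars, keep_traces = TRUE)
  vs_rest <- sympathetic_activity(0, 0, awake, pars)
  cc_star <- pars$tau_c * pars$k_cS * vs_rest
  cv_star <- pars$tau_v * pars$k_vS * (vs_rest + pars$k_v)
  tail_tr <- sim$trace[sim$trace$t > 80, ]
  expect_lt(max(abs(tail_tr$c_c - cc_star)) / cc_star, 1e-4)
  expect_lt(max(abs(tail_tr$c_v - cv_star)) / cv_star, 1e-4)
})

test_that("initial conditions start from the resting operating point", {
  sim <- simulate_cvs("awake", duration = 60, transient = 0, noise = FALSE,
                      keep_traces = TRUE)
  vs_rest <- sympathetic_activity(0, 0, awake, tab_params)
  expect_equal(sim$trace$c_c[1], tab_params$tau_c * tab_params$k_cS * vs_rest,
               tolerance = 1e-10)
  expect_equal(sim$trace$p[1], 80)
  expect_equal(sim$trace$phi[1], 0)
})

test_that("per-cycle pressure extrema bracket the trace and SP > DP", {
  sim <- simulate_cvs("awake", duration = 200, transient = 100, seed = 6)
  keep <- sim$beat_times > 100
  expect_true(all(sim$sp[keep] > sim$dp[keep]))
})

test_that("invalid settings are rejected", {
  expect_error(simulate_cvs("awake", duration = 100, transient = 90))
  expect_error(simulate_cvs("awake", duration = 100, transient = 10, dt = 0))
})
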