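test_that("cascade populations satisfy boundary conditions and conserve probability", {
  p0 <- populations(0, 100e-15, 94e-12)
  expect_equal(unname(p0), cbind(1, 0, 0), ignore_attr = TRUE)
  p_inf <- populations(1e-6, 100e-15, 94e-12)
  expect_equal(unname(p_inf[, "S0"]), 1, tolerance = 1e-12)
  withr::with_seed(3, {
    t <- sort(runif(50, 0, 1e-9))
    p <- populations(t, 100e-15, 94e-12)
    expect_identical(unname(rowSums(p)), rep(1, 50))  # machine exact
    expect_true(all(p >= -1e-15 & p <= 1 + 1e-15))
  })
  expect_error(populations(-1e-12, 1e-13, 1e-11), ">= 0")
})

test_that("cascade populations match a stiff ODE integration of the rate equations", {
  t_out <- c(0.05e-12, 0.2e-12, 1e-12, 20e-12, 200e-12)
  ours <- populations(t_out, 100e-15, 94e-12)
  oracle <- ode_populations(t_out, 100e-15, 94e-12)
  expect_equal(unname(ours), oracle, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("populations are continuous across the equal-rate switch-over", {
  tau <- 1e-12
  t <- seq(0, 1e-11, length.out = 50)
  just_below <- populations(t, tau, tau * (1 + 0.5e-9))  # limit formula
  just_above <- populations(t, tau, tau * (1 + 2e-9))    # generic formula
  expect_lt(max(abs(just_below - just_above)), 1e-7)
})

test_that("the Gaussian-convolved exponential has the right limits and area", {
  t <- seq(-1e-12, 5e-12, length.out = 400)
  tau <- 0.5e-12; sig <- 60e-15; t0 <- 0.2e-12
  # delta-IRF limit: a vanishing width reproduces the sharp exponential
  tiny <- 1e-17
  late <- t - t0 > 5 * tiny
  emg0 <- convolve_irf(t, tau, 2, t0, tiny)
  sharp <- convolve_irf(t, tau, 2, t0, 0)
  expect_equal(emg0[late], sharp[late], tolerance = 1e-9)
  emg <- convolve_irf(t, tau, 2, t0, sig)
  expect_true(all(is.finite(emg)) && all(emg >= 0))
  expect_equal(convolve_irf(t0, tau, 2, t0, 1e-15), 1, tolerance = 1e-2)  # A/2 at t0 for sigma << tau
  # area A * tau, independent of the IRF width (quadrature oracle);
  # integrate in ps so the integrand is O(1) for the adaptive rule
  for (s in c(0, 40e-15, 150e-15)) {
    area_ps <- integrate(function(x) convolve_irf(x * 1e-12, tau, 2, t0, s),
                         -2, 30, rel.tol = 1e-10, subdivisions = 500L)$value
    expect_equal(area_ps * 1e-12, 2 * tau, tolerance = 1e-6)
  }
  expect_error(convolve_irf(t, -1e-12, 1, 0, 0), "tau")
})

test_that("prompt and delayed model signals have the documented structure", {
  p <- paper_kinetic_params()
  # pre-pulse: baseline only
  expect_equal(prompt_signal(p, -2e-12), p$baseline_prompt, tolerance = 1e-12)
  expect_equal(delayed_signal(p, -2e-12), p$baseline_delayed, tolerance = 1e-12)
  # amp_s1 = 0: single EMG decay with tau_fast
  p1 <- p; p1$amp_s1 <- 0
  t <- seq(-0.5e-12, 2e-12, length.out = 100)
  expect_equal(prompt_signal(p1, t),
               p$baseline_prompt + convolve_irf(t, p$tau_fast, p$amp_s2,
                                                p$t0, p$irf_sigma))
  # for t >> tau_fast the prompt signal is the slow exponential alone
  tl <- seq(20e-12, 300e-12, length.out = 50)
  expect_equal(prompt_signal(p, tl),
               p$baseline_prompt + p$amp_s1 * exp(-tl / p$tau_slow),
               tolerance = 1e-3)
  # delayed channel: full recovery at long delay, monotone rise
  expect_equal(delayed_signal(p, 5e-9), p$baseline_delayed + p$amp_s0,
               tolerance = 1e-6)
  td <- seq(1e-12, 1e-9, length.out = 200)
  expect_true(all(diff(delayed_signal(p, td)) >= -1e-12))
})

test_that("noiseless transients are recovered to high precision by the joint fit", {
  truth <- paper_kinetic_params()
  del <- pump_probe_delays()
  pr <- generate_transient(truth, del, noise_model(scale = 0), "prompt")
  de <- generate_transient(truth, del, noise_model(scale = 0), "delayed")
  init <- truth
  init$tau_fast <- 3e-13; init$tau_slow <- 2e-11; init$t0 <- 2e-14
  fit <- fit_transients(pr, de, init = init, fixed = "irf_sigma")
  expect_true(fit$converged)
  for (nm in c("tau_fast", "tau_slow", "amp_s2", "amp_s1", "amp_s0")) {
    expect_equal(fit$params[[nm]], truth[[nm]], tolerance = 1e-6)
  }
  expect_lt(fit$redchi2, 1e-10)
})

test_that("a swapped initial guess converges to the same canonical optimum", {
  truth <- paper_kinetic_params()
  del <- pump_probe_delays()
  pr <- generate_transient(truth, del, noise_model(scale = 0.03, seed = 17),
                           "prompt")
  de <- generate_transient(truth, del, noise_model(scale = 0.03, seed = 18),
                           "delayed")
  init1 <- truth; init1$tau_fast <- 2e-13; init1$tau_slow <- 3e-11
  init2 <- truth; init2$tau_fast <- 3e-11; init2$tau_slow <- 2e-13  # swapped
  f1 <- fit_transients(pr, de, init = init1, fixed = "irf_sigma")
  f2 <- fit_transients(pr, de, init = init2, fixed = "irf_sigma")
  expect_lt(f2$params$tau_fast, f2$params$tau_slow)  # canonical ordering
  expect_equal(f2$params$tau_fast, f1$params$tau_fast, tolerance = 1e-4)
  expect_equal(f2$params$tau_slow, f1$params$tau_slow, tolerance = 1e-4)
})

test_that("the fit is invariant under signal rescaling and time-zero shifts", {
  truth <- paper_kinetic_params()
  del <- pump_probe_delays()
  pr <- generate_transient(truth, del, noise_model(scale = 0.05, seed = 21),
                           "prompt")
  init <- truth; init$tau_fast <- 2e-13; init$tau_slow <- 3e-11
  f0 <- fit_transients(pr, init = init, fixed = "irf_sigma")
  # rescale signal and uncertainties by 1000
  pr_scaled <- transient(pr$delay_s, pr$signal * 1000, pr$sigma * 1000,
                         "prompt")
  init_s <- init
  for (nm in c("amp_s2", "amp_s1", "baseline_prompt")) init_s[[nm]] <- init[[nm]] * 1000
  f_scaled <- fit_transients(pr_scaled, init = init_s, fixed = "irf_sigma")
  expect_equal(f_scaled$params$tau_fast, f0$params$tau_fast, tolerance = 1e-6)
  expect_equal(f_scaled$params$tau_slow, f0$params$tau_slow, tolerance = 1e-6)
  # shift all delays (and t0) by +5 ps
  pr_shift <- transient(pr$delay_s + 5e-12, pr$signal, pr$sigma, "prompt")
  init_t <- init; init_t$t0 <- 5e-12
  f_shift <- fit_transients(pr_shift, init = init_t, fixed = "irf_sigma")
  expect_equal(f_shift$params$tau_fast, f0$params$tau_fast, tolerance = 1e-6)
  expect_equal(f_shift$params$tau_slow, f0$params$tau_slow, tolerance = 1e-6)
  expect_equal(f_shift$params$t0 - 5e-12, f0$params$t0, tolerance = 1e-15)
})

test_that("degenerate and underdetermined inputs are flagged, not silently fitted", {
  del <- pump_probe_delays(n = 20)
  flat <- transient(del, rep(1, length(del)), channel = "prompt")
  fit <- fit_transients(flat, init = paper_kinetic_params())
  expect_false(fit$converged)
  expect_match(fit$message, "degenerate")
  tiny <- transient(del[1:5], 1:5, channel = "prompt")
  expect_error(fit_transients(tiny), "at least 8")
})
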