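test_that("the microcanonical rate is zero below the barrier and matches hand-built counts above it", {
  grid_min <- count_states(c(1000, 1500), emax = 5000, bin = 100)
  grid_ts <- count_states(1000, emax = 5000, bin = 100)
  expect_equal(rrkm_rate(0.40, grid_min, grid_ts, barrier_eV = 0.41), 0)

  # two-mode toy at E = 0.5 eV over a 0.1 eV barrier, from enumeration:
  # W_ts counts mode-1000 levels up to 0.4 eV; rho is the 100 cm^-1 window
  # population of the minimum around 0.5 eV, converted to states per eV
  cm <- dark_constants()[["cm1_per_eV"]]
  h <- dark_constants()[["h_eV_s"]]
  e_cm <- 0.5 * cm
  lo <- floor(e_cm / 100) * 100
  w_ts <- enum_sum_of_states(1000, 0.4 * cm)
  rho_eV <- enum_states_in_window(c(1000, 1500), lo, lo + 100) / 100 * cm
  expect_equal(rrkm_rate(0.5, grid_min, grid_ts, 0.1, sigma = 1),
               w_ts / (h * rho_eV))
  # symmetry factor scales linearly
  expect_equal(rrkm_rate(0.5, grid_min, grid_ts, 0.1, sigma = 2),
               2 * rrkm_rate(0.5, grid_min, grid_ts, 0.1, sigma = 1))
})

test_that("k(E) is nondecreasing and stable under bin refinement on a dense system", {
  # a molecule-sized mode count keeps every 1 cm^-1 bin populated over the
  # scan; sub-barrier the rate is identically zero, and just above the
  # barrier sparse-count fluctuations are expected, so the scan starts at
  # E0 + 0.1 eV as stated for the refinement property
  withr::with_seed(23, {
    freqs <- sort(runif(30, 50, 1500))
  })
  E0 <- 0.3
  emax_cm <- 2.4 * dark_constants()[["cm1_per_eV"]]
  E <- seq(E0 + 0.1, E0 + 2, by = 0.05)
  g1m <- count_states(freqs, emax_cm, bin = 1)
  g1t <- count_states(freqs[-1], emax_cm, bin = 1)
  k1 <- rrkm_rate(E, g1m, g1t, E0)
  expect_true(all(diff(k1) >= 0))
  expect_equal(rrkm_rate(E0 - 0.01, g1m, g1t, E0), 0)
  # refinement invariance: bin 2 vs bin 1 within 1%
  g2m <- count_states(freqs, emax_cm, bin = 2)
  g2t <- count_states(freqs[-1], emax_cm, bin = 2)
  k2 <- rrkm_rate(E, g2m, g2t, E0)
  expect_equal(k2, k1, tolerance = 0.01)
})

test_that("the thermal ensemble matches the closed-form harmonic mean energy", {
  freqs <- c(200, 500, 800, 1200, 1600)
  expect_equal(thermal_distribution(freqs, 0)$P, 1)  # T = 0 point mass
  for (T in c(150, 300, 600)) {
    ens <- thermal_distribution(freqs, T, bin = 1)
    expect_equal(sum(ens$P), 1, tolerance = 1e-9)
    kT_cm <- dark_constants()[["kB_eV_K"]] * T * dark_constants()[["cm1_per_eV"]]
    mean_cf <- sum(freqs / expm1(freqs / kT_cm))
    expect_equal(ensemble_mean_energy(ens), mean_cf, tolerance = 1,
                 ignore_attr = TRUE)  # within one bin width
  }
  expect_error(thermal_distribution(freqs, -10), ">= 0")
})

test_that("ensemble survival reduces to the analytic single- and two-component forms", {
  # degenerate ensemble: single exponential
  ens1 <- structure(list(temperature_K = 0, energies = 0, P = 1),
                    class = "thermal_ensemble")
  k <- 1e10
  rc <- structure(list(energies = c(0, 2), k = c(k, k), barrier_eV = 0.1,
                       sigma = 1), class = "rate_curve")
  tt <- seq(0, 5e-10, length.out = 101)
  s <- ensemble_survival(ens1, 3, 1.5, rc, tt)
  expect_equal(s$S, exp(-k * tt))

  # two-point 50/50 ensemble at rates k and 2k
  cm <- dark_constants()[["cm1_per_eV"]]
  ens2 <- structure(list(temperature_K = 300, energies = c(0, 0.2 * cm),
                         P = c(0.5, 0.5)), class = "thermal_ensemble")
  rc2 <- structure(list(energies = c(0, 0.2, 1), k = c(k, 2 * k, 2 * k),
                        barrier_eV = 0.1, sigma = 1), class = "rate_curve")
  s2 <- ensemble_survival(ens2, 3, 3, rc2, tt)
  expect_equal(s2$S, (exp(-k * tt) + exp(-2 * k * tt)) / 2)
  expect_equal(s2$S[1], 1)
  expect_true(all(diff(s2$S) <= 0))
  # bounded by the extreme single exponentials
  expect_true(all(s2$S <= exp(-k * tt) + 1e-12))
  expect_true(all(s2$S >= exp(-2 * k * tt) - 1e-12))
  # range error when the rate grid does not cover the ensemble
  expect_error(ensemble_survival(ens2, 5, 3, rc, tt), "cover")
})

test_that("the 1/e lifetime matches analytic and root-finding oracles", {
  k <- 1e10
  tt <- 10^seq(-12, -8, length.out = 400)
  tau <- statistical_lifetime(data.frame(time_s = tt, S = exp(-k * tt)))
  expect_equal(tau, 1e-10, tolerance = 1e-4)  # pure exponential: tau = 1/k

  mix <- function(t) (exp(-k * t) + exp(-2 * k * t)) / 2
  tau_mix <- statistical_lifetime(data.frame(time_s = tt, S = mix(tt)))
  oracle <- uniroot(function(t) mix(t) - exp(-1), c(1e-12, 1e-8),
                    tol = 1e-18)$root
  expect_equal(tau_mix, oracle, tolerance = 1e-3)

  expect_error(statistical_lifetime(data.frame(time_s = tt[1:3],
                                               S = exp(-k * tt[1:3]))),
               "widen")
})

test_that("statistical lifetimes fall with temperature and photon energy on a synthetic molecule", {
  fs <- generate_frequency_set(30, c(50, 3500), seed = 31, make_ts = TRUE)
  base <- rrkm_lifetime(fs$minimum, fs$transition_state, barrier_eV = 0.41,
                        temperature_K = 300, pump_nm = 400, aee_eV = 1.51)
  expect_true(base$tau_s > 0)
  expect_equal(base$survival$S[1], 1, tolerance = 1e-9)
  expect_true(all(diff(base$survival$S) <= 1e-15))
  hotter <- rrkm_lifetime(fs$minimum, fs$transition_state, 0.41, 500, 400, 1.51)
  bluer <- rrkm_lifetime(fs$minimum, fs$transition_state, 0.41, 300, 370, 1.51)
  expect_lt(hotter$tau_s, base$tau_s)
  expect_lt(bluer$tau_s, base$tau_s)
})
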