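test_that("simulated ridges sit at the channel energetics and closed channels vanish", {
  d <- fixture_diagram()
  hv <- seq(2.8, 4.6, by = 0.02)
  eke <- seq(0, 2.5, by = 0.01)
  sp <- simulate_pe2d(d, list(channel_spec("direct_d0")), hv, eke,
                      provenance = "measured")
  cut <- spectral_cut(sp, 4.28)
  expect_equal(peak_eke(cut), 4.28 - 2.63, tolerance = 0.005)  # half a bin

  # all amplitudes zero -> zero matrix
  sp0 <- simulate_pe2d(d, list(channel_spec("direct_d0", amplitude = 0)),
                       hv, eke)
  expect_true(all(sp0$intensity == 0))

  # two-photon channel contributes nothing where AEE(S1) + hv <= VDE(D0)
  hv_low <- seq(0.2, 2.0, by = 0.02)  # 1.51 + hv <= 2.63 for hv <= 1.12
  sp2 <- simulate_pe2d(d, list(channel_spec("two_photon_s1")), hv_low, eke,
                       provenance = "measured")
  closed <- hv_low <= 2.63 - 1.51
  expect_true(all(sp2$intensity[closed, ] == 0))
  expect_true(any(sp2$intensity[!closed, ] > 0))

  # simulation is deterministic
  sp_b <- simulate_pe2d(d, list(channel_spec("direct_d0")), hv, eke,
                        provenance = "measured")
  expect_identical(sp$intensity, sp_b$intensity)

  # missing threshold -> missing-state error
  d_min <- level_diagram(rbind(state_level("S0", "anion", 0)),
                         list(vde_d0 = 2.63, ade_d0 = 2.30))
  expect_error(simulate_pe2d(d_min, list(channel_spec("direct_d1n")), hv, eke),
               "vde_d1n")
})

test_that("spectral cuts extract exact columns and flag out-of-range requests", {
  d <- fixture_diagram()
  hv <- seq(3.0, 4.0, by = 0.1)
  eke <- seq(0, 2, by = 0.05)
  sp <- simulate_pe2d(d, list(channel_spec("direct_d0")), hv, eke)
  cut <- spectral_cut(sp, 3.5)
  expect_equal(attr(cut, "hv"), 3.5)
  expect_equal(cut$intensity, unname(sp$intensity[which(hv == 3.5), ]))
  expect_error(spectral_cut(sp, 5.0), "outside")
  # cut of a zero matrix is zero
  spz <- simulate_pe2d(d, list(channel_spec("direct_d0", amplitude = 0)),
                       hv, eke)
  expect_true(all(spectral_cut(spz, 3.5)$intensity == 0))
})

test_that("the S3 window broadens cuts as measured by the second moment", {
  d <- fixture_diagram()
  hv <- seq(3.3, 4.1, by = 0.05)
  eke <- seq(0, 2, by = 0.01)
  sp <- simulate_pe2d(d, list(channel_spec("direct_d0"),
                              channel_spec("s3_broadening", amplitude = 0.6)),
                      hv, eke)
  m2 <- function(cut) {
    w <- cut$intensity / sum(cut$intensity)
    mu <- sum(w * cut$eke)
    sum(w * (cut$eke - mu)^2)
  }
  expect_gt(m2(spectral_cut(sp, 3.75)), m2(spectral_cut(sp, 3.5)))
})

test_that("peak extraction interpolates to sub-bin accuracy with documented tie-breaking", {
  eke <- seq(0, 2, by = 0.02)
  gauss <- exp(-(eke - 0.45)^2 / (2 * 0.12^2))
  expect_equal(peak_eke(data.frame(eke = eke, intensity = gauss)), 0.45,
               tolerance = 0.01)
  # symmetric two-peak tie resolves to the lower-eKE peak
  two <- exp(-(eke - 0.5)^2 / (2 * 0.05^2)) + exp(-(eke - 1.5)^2 / (2 * 0.05^2))
  expect_equal(peak_eke(data.frame(eke = eke, intensity = two)), 0.5,
               tolerance = 0.01)
  expect_error(peak_eke(data.frame(eke = eke, intensity = 0 * eke)), "empty")
})

test_that("the simulated S1 probe feature reproduces the ~1.1 eV binding energy", {
  d <- fixture_diagram()
  hv_probe <- photon_energy(800)
  eke <- seq(0, 1.5, by = 0.005)
  sp <- simulate_pe2d(d, list(channel_spec("two_photon_s1", width = 0.1)),
                      hv = c(1.5, hv_probe, 1.6), eke, provenance = "measured")
  pk <- peak_eke(spectral_cut(sp, hv_probe))
  expect_equal(binding_energy_from_peak(hv_probe, pk), 1.1, tolerance = 0.05)
})

test_that("direct-ridge peak positions regress on photon energy with unit slope", {
  d <- fixture_diagram()
  hv <- seq(3.0, 4.6, by = 0.02)
  eke <- seq(0, 2.5, by = 0.01)
  sp <- simulate_pe2d(d, list(channel_spec("direct_d0", width = 0.1)), hv, eke,
                      provenance = "measured")
  peaks <- vapply(seq_along(hv),
                  function(i) peak_eke(data.frame(eke = eke,
                                                  intensity = sp$intensity[i, ])),
                  numeric(1))
  slope <- unname(coef(lm(peaks ~ hv))[2])
  expect_equal(slope, 1, tolerance = 0.01)
})
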