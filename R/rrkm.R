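#' Microcanonical RRKM / quasi-equilibrium rate constant
#'
#' Computes `k(E) = sigma * W'(E - E0) / (h * rho(E))`, the statistical
#' (quasi-equilibrium) rate for crossing a barrier `E0`, with `W'` the sum
#' of states of the transition state and `rho` the density of states of the
#' reactant minimum.  Below the barrier the rate is exactly zero.
#'
#' @param E Internal energy above the reactant zero-point level, eV
#'   (vectorised).
#' @param grid_min `state_count_grid` of the reactant minimum
#'   (from [count_states()]).
#' @param grid_ts `state_count_grid` of the transition state.
#' @param barrier_eV Barrier height `E0` in eV, > 0.
#' @param sigma Reaction-path symmetry/degeneracy factor, > 0 (default 1).
#' @return Rate constant(s) in s^-1.
#' @export
rrkm_rate <- function(E, grid_min, grid_ts, barrier_eV, sigma = 1) {
  stopifnot(inherits(grid_min, "state_count_grid"),
            inherits(grid_ts, "state_count_grid"))
  if (barrier_eV <= 0) stop("barrier_eV must be > 0", call. = FALSE)
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  k <- numeric(length(E))
  open <- E >= barrier_eV
  if (!any(open)) return(k)
  e_cm <- E[open] * .cm1_per_eV
  w_ts <- state_count_W(grid_ts, (E[open] - barrier_eV) * .cm1_per_eV)
  rho_eV <- state_count_rho(grid_min, e_cm) * .cm1_per_eV
  if (any(rho_eV == 0 & w_ts > 0)) {
    stop("zero density of states at an open-channel energy; use a coarser bin",
         call. = FALSE)
  }
  kk <- sigma * w_ts / (.h_eV_s * rho_eV)
  kk[w_ts == 0] <- 0
  k[open] <- kk
  k
}

#' Microcanonical rate curve k(E)
#'
#' Evaluates [rrkm_rate()] on an energy grid and packages the result.
#'
#' @param energies Energy grid in eV (internal energy of the reactant above
#'   its zero-point level), strictly increasing.
#' @inheritParams rrkm_rate
#' @return Object of class `rate_curve` with elements `energies`, `k`,
#'   `barrier_eV`, `sigma`.
#' @export
rate_curve <- function(energies, grid_min, grid_ts, barrier_eV, sigma = 1) {
  k <- rrkm_rate(energies, grid_min, grid_ts, barrier_eV, sigma)
  structure(list(energies = energies, k = k, barrier_eV = barrier_eV,
                 sigma = sigma), class = "rate_curve")
}

#' @export
print.rate_curve <- function(x, ...) {
  cat(sprintf("rate_curve: %d energies, barrier %.3f eV, sigma %g, k up to %.3g s^-1\n",
              length(x$energies), x$barrier_eV, x$sigma, max(x$k)))
  invisible(x)
}

#' Canonical (thermal) vibrational energy distribution
#'
#' Boltzmann distribution over the harmonic vibrational levels of the
#' electronic ground state, `P(E) \propto rho(E) exp(-E / kB T)`, binned on
#' the state-count grid.  This is the internal-energy distribution of the
#' stored-ion ensemble before photoexcitation.  `T = 0` gives a point mass
#' at `E = 0`.
#'
#' @param freqs_s0 [frequency_set()] (or numeric vector, cm^-1) of the
#'   ground-state minimum.
#' @param temperature_K Temperature in K, >= 0.
#' @param emax Grid upper edge in cm^-1; by default generous enough that the
#'   truncated Boltzmann tail is negligible.
#' @param bin Grid bin width in cm^-1.
#' @return Object of class `thermal_ensemble` with elements `temperature_K`,
#'   `energies` (cm^-1) and `P` (probabilities summing to 1).
#' @export
thermal_distribution <- function(freqs_s0, temperature_K, emax = NULL, bin = 1) {
  if (inherits(freqs_s0, "frequency_set")) freqs_s0 <- freqs_s0$frequencies
  if (temperature_K < 0) stop("temperature must be >= 0", call. = FALSE)
  if (temperature_K == 0) {
    return(structure(list(temperature_K = 0, energies = 0, P = 1),
                     class = "thermal_ensemble"))
  }
  kT_cm <- .kB_eV_K * temperature_K * .cm1_per_eV
  mean_cf <- sum(freqs_s0 / expm1(freqs_s0 / kT_cm))  # closed-form harmonic mean energy
  if (is.null(emax)) emax <- ceiling((3 * mean_cf + 25 * kT_cm + 1000) / bin) * bin
  grid <- count_states(freqs_s0, emax, bin)
  logw <- ifelse(grid$counts > 0, log(grid$counts) - grid$energies / kT_cm, -Inf)
  w <- exp(logw - max(logw))
  structure(list(temperature_K = temperature_K, energies = grid$energies,
                 P = w / sum(w)), class = "thermal_ensemble")
}

#' Mean internal energy of a thermal ensemble
#'
#' @param ensemble A [thermal_distribution()] result.
#' @return Mean vibrational energy in cm^-1.
#' @export
ensemble_mean_energy <- function(ensemble) {
  sum(ensemble$energies * ensemble$P)
}

#' Ensemble survival probability of the trapped excited state
#'
#' Each member of the ground-state thermal ensemble that absorbs a pump
#' photon `hv` arrives in the excited state with internal energy
#' `E = Ev + hv - AEE` above the excited-state minimum, and decays with the
#' microcanonical rate `k(E)`.  The ensemble survival is the rate-weighted
#' mixture of exponentials `S(t) = sum P(Ev) exp(-k(E) t)`.
#'
#' @param ensemble A [thermal_distribution()] result.
#' @param hv Pump photon energy in eV, >= `aee_eV`.
#' @param aee_eV Adiabatic excitation energy of the trapped state, eV.
#' @param rates A [rate_curve()] whose grid covers all shifted energies.
#' @param times Times (s) at which to evaluate the survival.
#' @param p_floor Ensemble members with probability below `p_floor` times
#'   the maximum are dropped (and the distribution renormalised).
#' @return Data frame with columns `time_s` and `S`.
#' @export
ensemble_survival <- function(ensemble, hv, aee_eV, rates, times,
                              p_floor = 1e-14) {
  stopifnot(inherits(ensemble, "thermal_ensemble"),
            inherits(rates, "rate_curve"))
  if (hv < aee_eV) stop("hv must be >= the adiabatic excitation energy", call. = FALSE)
  keep <- ensemble$P >= p_floor * max(ensemble$P)
  P <- ensemble$P[keep] / sum(ensemble$P[keep])
  E <- ensemble$energies[keep] / .cm1_per_eV + (hv - aee_eV)
  if (min(E) < min(rates$energies) - 1e-9 || max(E) > max(rates$energies) + 1e-9) {
    stop("rate curve does not cover the excited-state energies; extend its grid",
         call. = FALSE)
  }
  k <- stats::approx(rates$energies, rates$k, xout = E, rule = 2)$y
  S <- as.vector(crossprod(P, exp(-outer(k, times))))
  data.frame(time_s = times, S = S)
}

#' 1/e lifetime of a survival curve
#'
#' The ensemble decay is generally non-exponential; the reported lifetime is
#' the time at which the survival crosses 1/e, found by linear interpolation
#' in log S between the bracketing samples.
#'
#' @param survival Data frame with columns `time_s` and `S`
#'   (from [ensemble_survival()]), with `S` nonincreasing.
#' @return Lifetime in seconds.
#' @export
statistical_lifetime <- function(survival) {
  t <- survival$time_s; S <- survival$S
  target <- exp(-1)
  i <- which(S <= target)
  if (length(i) == 0) {
    stop("survival does not reach 1/e in the sampled window; widen the time window",
         call. = FALSE)
  }
  i2 <- i[1L]
  if (i2 == 1L) return(t[1L])
  i1 <- i2 - 1L
  f <- (log(S[i1]) - log(target)) / (log(S[i1]) - log(S[i2]))
  t[i1] + f * (t[i2] - t[i1])
}

#' Statistical lifetime of a trapped excited state
#'
#' Full quasi-equilibrium pipeline: count states of the excited-state
#' minimum and of the transition state, thermally populate the ground-state
#' vibrational manifold at `temperature_K`, promote the ensemble with a pump
#' photon, average the microcanonical decay, and report the 1/e lifetime.
#'
#' @param freqs_min [frequency_set()] of the excited-state minimum (also
#'   used for the pre-excitation thermal distribution unless `freqs_s0`
#'   is given).
#' @param freqs_ts [frequency_set()] of the transition state (one mode
#'   fewer).
#' @param barrier_eV Barrier height in eV (0.41 eV for the meta-HBDI
#'   S1/S0 conical intersection pathway).
#' @param temperature_K Ion temperature in K.
#' @param pump_nm Pump wavelength in nm.
#' @param aee_eV Adiabatic excitation energy of the trapped state, eV.
#' @param freqs_s0 Optional separate ground-state frequency set.
#' @param sigma Symmetry factor (default 1).
#' @param bin State-count bin width, cm^-1 (default 1).
#' @param times Optional time grid (s); by default a logarithmic grid
#'   bracketing the mean decay rate.
#' @return Object of class `lifetime_result`: `tau_s`, `temperature_K`,
#'   `pump_nm`, `survival` (data frame), `rates` (the [rate_curve()]).
#' @export
rrkm_lifetime <- function(freqs_min, freqs_ts, barrier_eV, temperature_K,
                          pump_nm, aee_eV, freqs_s0 = freqs_min, sigma = 1,
                          bin = 1, times = NULL) {
  hv <- photon_energy(pump_nm)
  if (hv < aee_eV) {
    stop("pump photon does not reach the trapped state", call. = FALSE)
  }
  ens <- thermal_distribution(freqs_s0, temperature_K, bin = bin)
  shift_cm <- (hv - aee_eV) * .cm1_per_eV
  emax_cm <- max(ens$energies) + shift_cm + 10 * bin
  grid_min <- count_states(freqs_min, emax_cm, bin)
  grid_ts <- count_states(freqs_ts, max(emax_cm - barrier_eV * .cm1_per_eV, bin),
                          bin)
  e_grid <- ens$energies / .cm1_per_eV + (hv - aee_eV)
  rates <- rate_curve(e_grid, grid_min, grid_ts, barrier_eV, sigma)
  if (is.null(times)) {
    keep <- ens$P >= 1e-14 * max(ens$P)
    k_mean <- sum(ens$P[keep] * rates$k[keep]) / sum(ens$P[keep])
    if (k_mean <= 0) {
      stop("ensemble decay rate is zero: all members lie below the barrier",
           call. = FALSE)
    }
    times <- c(0, 10^seq(log10(1 / k_mean) - 4, log10(1 / k_mean) + 4,
                         length.out = 321))
  }
  surv <- ensemble_survival(ens, hv, aee_eV, rates, times)
  structure(list(tau_s = statistical_lifetime(surv),
                 temperature_K = temperature_K, pump_nm = pump_nm,
                 aee_eV = aee_eV, barrier_eV = barrier_eV,
                 survival = surv, rates = rates, ensemble = ens),
            class = "lifetime_result")
}

#' @export
print.lifetime_result <- function(x, ...) {
  cat(sprintf("statistical lifetime: %.3g s (%.1f ps) at %g K, %g nm pump, barrier %.2f eV\n",
              x$tau_s, x$tau_s * 1e12, x$temperature_K, x$pump_nm,
              x$barrier_eV))
  invisible(x)
}
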