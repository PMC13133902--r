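#' Noise model for synthetic data
#'
#' @param kind `"multiplicative_lognormal"` (scale = sdlog of the lognormal
#'   factor), `"additive_gaussian"` (scale = standard deviation) or
#'   `"poisson_counts"` (scale ignored; the model curve is the Poisson
#'   mean).
#' @param scale Noise scale, >= 0.
#' @param seed Integer seed; identical seed and parameters give identical
#'   output.
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(kind = c("multiplicative_lognormal",
                                 "additive_gaussian", "poisson_counts"),
                        scale = 0.05, seed = 1) {
  kind <- match.arg(kind)
  if (scale < 0) stop("noise scale must be >= 0", call. = FALSE)
  structure(list(kind = kind, scale = scale, seed = as.integer(seed)),
            class = "noise_model")
}

.apply_noise <- function(mu, noise) {
  switch(noise$kind,
         multiplicative_lognormal = {
           if (noise$scale == 0) return(list(y = mu, sigma = rep(NA_real_, length(mu))))
           f <- .with_seed(noise$seed, stats::rnorm(length(mu), 0, noise$scale))
           list(y = mu * exp(f), sigma = abs(mu) * noise$scale)
         },
         additive_gaussian = {
           if (noise$scale == 0) return(list(y = mu, sigma = rep(NA_real_, length(mu))))
           e <- .with_seed(noise$seed, stats::rnorm(length(mu), 0, noise$scale))
           list(y = mu + e, sigma = rep(noise$scale, length(mu)))
         },
         poisson_counts = {
           y <- .with_seed(noise$seed, stats::rpois(length(mu), pmax(mu, 0)))
           list(y = as.numeric(y), sigma = sqrt(pmax(mu, 1)))
         })
}

#' Generate a synthetic pump-probe transient
#'
#' Evaluates the sequential-model signal for the requested channel and
#' corrupts it with the chosen noise model.  The generating parameters are
#' stored in the `true_params` attribute so recovery tests never re-derive
#' truth from noisy data.
#'
#' @param params A [kinetic_params()].
#' @param delays Delays in seconds, strictly increasing
#'   (see [pump_probe_delays()]).
#' @param noise A [noise_model()].
#' @param channel `"prompt"` or `"delayed"`.
#' @return A [transient()] with attribute `true_params`.
#' @export
generate_transient <- function(params, delays, noise,
                               channel = c("prompt", "delayed")) {
  channel <- match.arg(channel)
  mu <- if (channel == "prompt") prompt_signal(params, delays)
        else delayed_signal(params, delays)
  ns <- .apply_noise(mu, noise)
  out <- transient(delays, ns$y, sigma = ns$sigma, channel = channel)
  attr(out, "true_params") <- params
  out
}

#' Generate a synthetic laser power-dependence series
#'
#' @param c0 Prefactor of the power law `y = c0 * P^n`.
#' @param n True photon order.
#' @param energies Pulse energies, > 0.
#' @param noise A [noise_model()].
#' @param wavelength_nm Wavelength tag.
#' @return A [power_series()] with attribute `true_exponent`.
#' @export
generate_power_series <- function(c0, n, energies, noise,
                                  wavelength_nm = NA_real_) {
  if (n <= 0) stop("photon order must be > 0", call. = FALSE)
  mu <- c0 * energies^n
  ns <- .apply_noise(mu, noise)
  out <- power_series(energies, ns$y, sigma = ns$sigma,
                      wavelength_nm = wavelength_nm)
  attr(out, "true_exponent") <- n
  out
}

#' Generate a synthetic harmonic frequency set
#'
#' Draws `n_modes` frequencies uniformly over `range_cm1` (sorted), standing
#' in for a molecule's unavailable normal-mode analysis.  The optional
#' transition-state set removes the lowest mode (the reaction coordinate)
#' and perturbs the remaining modes by a seeded uniform +/- `ts_perturb`
#' fraction.
#'
#' @param n_modes Number of modes of the minimum, >= 2.
#' @param range_cm1 Frequency range in cm^-1 (default 50-3500, the span of
#'   a mid-size organic chromophore).
#' @param seed Integer seed.
#' @param make_ts Also generate the paired transition-state set?
#' @param ts_perturb Fractional perturbation of the TS modes.
#' @return A [frequency_set()], or when `make_ts = TRUE` a list with
#'   elements `minimum` and `transition_state`.
#' @export
#' @examples
#' fs <- generate_frequency_set(78, seed = 11, make_ts = TRUE)
#' length(fs$transition_state$frequencies)  # 77
generate_frequency_set <- function(n_modes, range_cm1 = c(50, 3500), seed = 1,
                                   make_ts = FALSE, ts_perturb = 0.1) {
  if (n_modes < 2) stop("need at least 2 modes", call. = FALSE)
  if (any(range_cm1 <= 0) || diff(range_cm1) <= 0) {
    stop("range_cm1 must be positive and increasing", call. = FALSE)
  }
  draw <- .with_seed(seed, {
    f <- sort(stats::runif(n_modes, range_cm1[1], range_cm1[2]))
    pert <- stats::runif(n_modes - 1, -ts_perturb, ts_perturb)
    list(f = f, pert = pert)
  })
  minimum <- frequency_set(draw$f, role = "minimum")
  if (!make_ts) return(minimum)
  ts <- frequency_set(draw$f[-1] * (1 + draw$pert), role = "transition_state")
  list(minimum = minimum, transition_state = ts)
}

#' Poisson-sample a simulated 2D photoelectron spectrum
#'
#' Emulates measured count statistics: the normalised intensity is scaled so
#' it sums to `total_counts` and each pixel is replaced by a Poisson draw.
#'
#' @param spec A `pe_spectrum_2d` from [simulate_pe2d()].
#' @param total_counts Expected total number of electrons, > 0.
#' @param seed Integer seed.
#' @return A `pe_spectrum_2d` whose intensity matrix holds nonnegative
#'   integer counts.
#' @export
generate_pe_counts <- function(spec, total_counts, seed = 1) {
  stopifnot(inherits(spec, "pe_spectrum_2d"))
  if (total_counts <= 0) stop("total_counts must be > 0", call. = FALSE)
  s <- sum(spec$intensity)
  lambda <- if (s > 0) spec$intensity / s * total_counts else spec$intensity
  counts <- .with_seed(seed, stats::rpois(length(lambda), lambda))
  out <- spec
  out$intensity <- matrix(as.numeric(counts), nrow(lambda), ncol(lambda))
  out$components <- NULL
  out
}

#' Seeded lifetime-recovery study for the sequential kinetic model
#'
#' Generates `n_replicates` prompt+delayed transient pairs from the true
#' parameters, fits each pair jointly with [fit_transients()], and collects
#' the recovered lifetimes.  This is the synthetic stand-in for repeating
#' the pump-probe experiment.
#'
#' @param n_replicates Number of synthetic experiment replicates.
#' @param true_params Generating [kinetic_params()]; defaults to the
#'   meta-HBDI values (100 fs fast, 94 ps slow, 80 fs IRF).
#' @param delays Delay grid in seconds.
#' @param noise_scale Multiplicative lognormal noise sdlog (default 0.05,
#'   i.e. 5 percent scatter).
#' @param seed Base integer seed; replicate r uses seeds
#'   `seed + 2r` / `seed + 2r + 1` for its two channels.
#' @param fixed Parameters held at truth during fitting; by default the
#'   independently calibrated IRF width.
#' @return Data frame with one row per replicate: recovered `tau_fast`,
#'   `tau_slow` (s), their standard errors, `converged`, `redchi2`.
#' @export
lifetime_recovery_study <- function(n_replicates = 100,
                                    true_params = kinetic_params(
                                      tau_fast = 100e-15, tau_slow = 94e-12,
                                      amp_s2 = 1, amp_s1 = 0.5, amp_s0 = 1,
                                      baseline_prompt = 0.02,
                                      baseline_delayed = 0.02,
                                      t0 = 0, irf_sigma = 80e-15),
                                    delays = pump_probe_delays(),
                                    noise_scale = 0.05, seed = 1,
                                    fixed = "irf_sigma") {
  init <- true_params
  init$tau_fast <- 2e-13; init$tau_slow <- 3e-11  # generic, away from truth
  rows <- lapply(seq_len(n_replicates), function(r) {
    pr <- generate_transient(true_params, delays,
                             noise_model("multiplicative_lognormal",
                                         noise_scale, seed + 2L * r),
                             channel = "prompt")
    de <- generate_transient(true_params, delays,
                             noise_model("multiplicative_lognormal",
                                         noise_scale, seed + 2L * r + 1L),
                             channel = "delayed")
    fit <- fit_transients(pr, de, init = init, fixed = fixed)
    data.frame(replicate = r,
               tau_fast = fit$params$tau_fast,
               tau_slow = fit$params$tau_slow,
               se_tau_fast = if (!is.null(fit$se)) fit$se[["tau_fast"]] else NA_real_,
               se_tau_slow = if (!is.null(fit$se)) fit$se[["tau_slow"]] else NA_real_,
               converged = fit$converged, redchi2 = fit$redchi2)
  })
  do.call(rbind, rows)
}
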