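#' Parameters of the sequential three-state kinetic model
#'
#' The model is a sequential cascade S2 -> S1 -> S0 following impulsive
#' excitation into S2.  Prompt action (fragmentation within ~10 us of the
#' probe) monitors the excited states; delayed action (ms scale statistical
#' decay) monitors the ground-state recovery.
#'
#' @param tau_fast S2 -> S1 lifetime in seconds, > 0.
#' @param tau_slow S1 -> S0 lifetime in seconds, > 0.
#' @param amp_s2,amp_s1 Prompt detection weights of S2 and S1, >= 0.
#' @param amp_s0 Delayed detection weight of the recovered ground state, >= 0.
#' @param baseline_prompt,baseline_delayed Constant baselines per channel.
#' @param t0 Time zero (s).
#' @param irf_sigma Gaussian instrument-response width (s), >= 0.
#' @return Object of class `kinetic_params` (a named list).
#' @export
#' @examples
#' kinetic_params(tau_fast = 100e-15, tau_slow = 94e-12)
kinetic_params <- function(tau_fast, tau_slow, amp_s2 = 1, amp_s1 = 1,
                           amp_s0 = 1, baseline_prompt = 0,
                           baseline_delayed = 0, t0 = 0,
                           irf_sigma = 80e-15) {
  if (tau_fast <= 0 || tau_slow <= 0) stop("lifetimes must be > 0", call. = FALSE)
  if (irf_sigma < 0) stop("irf_sigma must be >= 0", call. = FALSE)
  if (amp_s2 < 0 || amp_s1 < 0 || amp_s0 < 0) {
    stop("detection weights must be >= 0", call. = FALSE)
  }
  structure(list(tau_fast = tau_fast, tau_slow = tau_slow, amp_s2 = amp_s2,
                 amp_s1 = amp_s1, amp_s0 = amp_s0,
                 baseline_prompt = baseline_prompt,
                 baseline_delayed = baseline_delayed, t0 = t0,
                 irf_sigma = irf_sigma), class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf("kinetic_params: tau_fast %.3g s, tau_slow %.3g s, IRF sigma %.3g s, t0 %.3g s\n",
              x$tau_fast, x$tau_slow, x$irf_sigma, x$t0))
  cat(sprintf("  amps S2/S1/S0: %.3g/%.3g/%.3g, baselines %.3g/%.3g\n",
              x$amp_s2, x$amp_s1, x$amp_s0, x$baseline_prompt,
              x$baseline_delayed))
  invisible(x)
}

#' Populations of the sequential S2 -> S1 -> S0 cascade
#'
#' Analytic solution of the rate equations with unit population in S2 at
#' `t = 0`:
#' `P_S2 = exp(-k1 t)`,
#' `P_S1 = k1/(k2 - k1) (exp(-k1 t) - exp(-k2 t))`,
#' `P_S0 = 1 - P_S2 - P_S1`.
#' When the two rates coincide (relative difference below 1e-9) the
#' degenerate limit `P_S1 = k t exp(-k t)` is used.
#'
#' @param t Times in seconds, >= 0 (the unconvolved model is one-sided).
#' @param tau_fast,tau_slow Lifetimes in seconds, > 0.
#' @return Matrix with columns `S2`, `S1`, `S0`; rows sum to 1 exactly.
#' @export
populations <- function(t, tau_fast, tau_slow) {
  if (tau_fast <= 0 || tau_slow <= 0) stop("lifetimes must be > 0", call. = FALSE)
  if (any(t < 0)) stop("t must be >= 0 for the unconvolved model", call. = FALSE)
  k1 <- 1 / tau_fast; k2 <- 1 / tau_slow
  p_s2 <- exp(-k1 * t)
  p_s1 <- if (abs(k1 - k2) / k1 < 1e-9) {
    k1 * t * exp(-k1 * t)
  } else {
    k1 / (k2 - k1) * (exp(-k1 * t) - exp(-k2 * t))
  }
  cbind(S2 = p_s2, S1 = p_s1, S0 = 1 - p_s2 - p_s1)
}

#' Exponential decay convolved with a Gaussian instrument response
#'
#' Closed-form exponentially modified Gaussian: the convolution of
#' `A exp(-(t - t0)/tau) H(t - t0)` with a unit-area Gaussian of width
#' `irf_sigma`.  Evaluated in log space so it stays finite far into the
#' pre-pulse and tail regions.  `irf_sigma = 0` reduces to the sharp-onset
#' exponential.
#'
#' @param t Times (s).
#' @param tau Decay time (s), > 0.
#' @param amplitude Pre-exponential amplitude.
#' @param t0 Time zero (s).
#' @param irf_sigma Gaussian IRF width (s), >= 0.
#' @return Signal values at `t`.
#' @export
convolve_irf <- function(t, tau, amplitude = 1, t0 = 0, irf_sigma = 0) {
  if (tau <= 0) stop("tau must be > 0", call. = FALSE)
  if (irf_sigma < 0) stop("irf_sigma must be >= 0", call. = FALSE)
  td <- t - t0
  if (irf_sigma == 0) {
    out <- numeric(length(t))
    on <- td >= 0
    out[on] <- amplitude * exp(-td[on] / tau)
    return(out)
  }
  h <- irf_sigma^2 / (2 * tau^2) - td / tau
  g <- (irf_sigma / tau - td / irf_sigma) / sqrt(2)
  # log(erfc(g)) via the normal tail keeps exp(h)*erfc(g) stable everywhere
  log_erfc <- log(2) + stats::pnorm(g * sqrt(2), lower.tail = FALSE,
                                    log.p = TRUE)
  amplitude / 2 * exp(h + log_erfc)
}

# IRF-convolved populations; the S1 difference-of-exponentials and the S0
# step are assembled from convolve_irf components (convolution is linear).
.convolved_populations <- function(p, t) {
  k1 <- 1 / p$tau_fast; k2 <- 1 / p$tau_slow
  if (abs(k1 - k2) / k1 < 1e-9) k2 <- k1 * (1 - 1e-7)
  a <- k1 / (k2 - k1)
  c1 <- convolve_irf(t, 1 / k1, 1, p$t0, p$irf_sigma)
  c2 <- convolve_irf(t, 1 / k2, 1, p$t0, p$irf_sigma)
  step <- if (p$irf_sigma == 0) {
    as.numeric(t >= p$t0)
  } else {
    stats::pnorm((t - p$t0) / p$irf_sigma)
  }
  s1 <- a * (c1 - c2)
  list(S2 = c1, S1 = s1, S0 = step - c1 - s1)
}

#' Prompt-channel model signal
#'
#' The prompt action probes the excited states:
#' `baseline + IRF x (amp_s2 P_S2 + amp_s1 P_S1)`.
#'
#' @param params A [kinetic_params()].
#' @param t Pump-probe delays in seconds.
#' @return Model signal at `t`.
#' @export
prompt_signal <- function(params, t) {
  cp <- .convolved_populations(params, t)
  params$baseline_prompt + params$amp_s2 * cp$S2 + params$amp_s1 * cp$S1
}

#' Delayed-channel model signal
#'
#' The delayed action monitors ground-state recovery:
#' `baseline + IRF x amp_s0 P_S0`, which rises with the slow lifetime.
#'
#' @inheritParams prompt_signal
#' @return Model signal at `t`.
#' @export
delayed_signal <- function(params, t) {
  cp <- .convolved_populations(params, t)
  params$baseline_delayed + params$amp_s0 * cp$S0
}

#' Pump-probe action transient
#'
#' @param delays Delays in seconds, strictly increasing.
#' @param signal Yield (counts or normalised).
#' @param sigma Optional per-point 1-sigma uncertainties, > 0.
#' @param channel `"prompt"` or `"delayed"`.
#' @return Data frame of class `transient` with columns `delay_s`, `signal`,
#'   `sigma`.
#' @export
transient <- function(delays, signal, sigma = NULL,
                      channel = c("prompt", "delayed")) {
  channel <- match.arg(channel)
  if (any(diff(delays) <= 0)) stop("delays must be strictly increasing", call. = FALSE)
  if (length(signal) != length(delays)) stop("signal/delays length mismatch", call. = FALSE)
  if (is.null(sigma)) sigma <- rep(NA_real_, length(delays))
  if (any(!is.na(sigma) & sigma <= 0)) stop("sigma must be > 0 where given", call. = FALSE)
  out <- data.frame(delay_s = delays, signal = signal, sigma = sigma)
  attr(out, "channel") <- channel
  class(out) <- c("transient", class(out))
  out
}

.param_names <- c("tau_fast", "tau_slow", "amp_s2", "amp_s1", "amp_s0",
                  "baseline_prompt", "baseline_delayed", "t0", "irf_sigma")
.log_params <- c("tau_fast", "tau_slow", "irf_sigma")

.params_to_theta <- function(params, free) {
  vapply(free, function(nm) {
    v <- params[[nm]]
    if (nm %in% .log_params) log(v) else v
  }, numeric(1))
}

.theta_to_params <- function(theta, free, base) {
  p <- base
  for (i in seq_along(free)) {
    nm <- free[i]
    p[[nm]] <- unname(if (nm %in% .log_params) exp(theta[i]) else theta[i])
  }
  p
}

# swap tau_fast/tau_slow and remap prompt amplitudes so the model curve is
# unchanged (the two-exponential span is symmetric under relabelling)
.canonicalize <- function(p) {
  if (p$tau_fast <= p$tau_slow) return(p)
  k1 <- 1 / p$tau_fast; k2 <- 1 / p$tau_slow
  a <- k1 / (k2 - k1)
  C1 <- p$amp_s2 + p$amp_s1 * a   # coefficient of exp(-k1 t)
  C2 <- -p$amp_s1 * a             # coefficient of exp(-k2 t)
  k1n <- k2; k2n <- k1
  an <- k1n / (k2n - k1n)
  p$amp_s1 <- -C1 / an
  p$amp_s2 <- C1 + C2
  p$tau_fast <- 1 / k1n
  p$tau_slow <- 1 / k2n
  p
}

#' Jointly fit prompt and delayed transients with the sequential model
#'
#' Weighted nonlinear least squares (Levenberg-Marquardt via
#' \code{minpack.lm}) of the sequential three-state model to a prompt
#' transient and, optionally, a delayed transient.  Both channels share the
#' lifetimes, `t0` and the IRF width; each has its own amplitude(s) and
#' baseline.  Lifetimes and the IRF width are optimised in log space so
#' positivity is structural.  After convergence the labels are canonically
#' ordered (`tau_fast <= tau_slow`) and the fit is restarted once from the
#' reordered optimum so the covariance refers to the canonical labels.
#'
#' @param prompt A [transient()] with channel `"prompt"`.
#' @param delayed Optional [transient()] with channel `"delayed"`.
#' @param init A [kinetic_params()] with starting values, or `NULL` for
#'   data-driven defaults.
#' @param fixed Character vector of parameter names to hold at their `init`
#'   values (e.g. `"irf_sigma"` when the cross-correlation was measured
#'   independently).
#' @param max_iter Maximum Levenberg-Marquardt iterations.
#' @param tau_fast_starts Multipliers on the initial fast lifetime used as
#'   additional starting points; multiexponential objectives have a local
#'   minimum where the fast component collapses below the sampling grid,
#'   and the restart with the lowest deviance wins.
#' @return Object of class `transient_fit`: `params` (fitted
#'   [kinetic_params()]), `se` (1-sigma uncertainties on the natural scale),
#'   `cov` (covariance, natural scale), `redchi2`, `converged`, `message`.
#'   Non-convergence and degenerate data are flagged, never silent.
#' @export
fit_transients <- function(prompt, delayed = NULL, init = NULL,
                           fixed = character(), max_iter = 200,
                           tau_fast_starts = c(1, 0.2, 5, 25)) {
  stopifnot(inherits(prompt, "transient"))
  n_pts <- nrow(prompt) + if (is.null(delayed)) 0L else nrow(delayed)
  if (n_pts < 8) stop("need at least 8 data points", call. = FALSE)
  sd_all <- stats::sd(c(prompt$signal,
                        if (!is.null(delayed)) delayed$signal))
  if (!is.finite(sd_all) || sd_all == 0) {
    return(structure(list(params = init, se = NULL, cov = NULL,
                          redchi2 = NA_real_, converged = FALSE,
                          message = "degenerate data: constant signal"),
                     class = "transient_fit"))
  }
  if (is.null(init)) {
    rng <- max(prompt$signal) - min(prompt$signal)
    init <- kinetic_params(
      tau_fast = 2e-13, tau_slow = 3e-11,
      amp_s2 = rng, amp_s1 = rng / 2,
      amp_s0 = if (is.null(delayed)) 1 else max(delayed$signal) - min(delayed$signal),
      baseline_prompt = min(prompt$signal),
      baseline_delayed = if (is.null(delayed)) 0 else min(delayed$signal),
      t0 = 0)
  }
  if (init$tau_fast <= 0 || init$tau_slow <= 0) {
    stop("initial lifetimes must be positive", call. = FALSE)
  }
  bad <- setdiff(fixed, .param_names)
  if (length(bad)) stop("unknown parameter name(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  free <- setdiff(.param_names, fixed)
  if (is.null(delayed)) free <- setdiff(free, c("amp_s0", "baseline_delayed"))
  if ("irf_sigma" %in% free && init$irf_sigma <= 0) {
    stop("irf_sigma must be fixed when its initial value is 0", call. = FALSE)
  }
  w_p <- ifelse(is.na(prompt$sigma), 1, prompt$sigma)
  w_d <- if (!is.null(delayed)) ifelse(is.na(delayed$sigma), 1, delayed$sigma)
  resid_fn <- function(theta) {
    p <- .theta_to_params(theta, free, init)
    if (!all(is.finite(unlist(p)))) return(rep(1e8, n_pts))
    r <- (prompt$signal - prompt_signal(p, prompt$delay_s)) / w_p
    if (!is.null(delayed)) {
      r <- c(r, (delayed$signal - delayed_signal(p, delayed$delay_s)) / w_d)
    }
    ifelse(is.finite(r), r, 1e8)
  }
  run_lm <- function(start_params) {
    minpack.lm::nls.lm(par = .params_to_theta(start_params, free),
                       fn = resid_fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = max_iter, ftol = 1e-13, ptol = 1e-13))
  }
  res <- NULL
  starts <- if ("tau_fast" %in% free) tau_fast_starts else 1
  for (mult in starts) {
    start <- init
    start$tau_fast <- init$tau_fast * mult
    cand <- run_lm(start)
    if (is.null(res) || cand$deviance < res$deviance) res <- cand
  }
  p_hat <- .theta_to_params(res$par, free, init)
  if (p_hat$tau_fast > p_hat$tau_slow &&
      all(c("tau_fast", "tau_slow") %in% free)) {
    res <- run_lm(.canonicalize(p_hat))
    p_hat <- .theta_to_params(res$par, free, init)
  }
  converged <- res$info %in% 1:4
  n_free <- length(free)
  dof <- n_pts - n_free
  redchi2 <- res$deviance / dof
  # res$hessian is J'J at the optimum (minpack.lm convention)
  cov_theta <- tryCatch(chol2inv(chol(res$hessian)) * redchi2,
                        error = function(e) NULL)
  se <- cov <- NULL
  if (!is.null(cov_theta)) {
    # delta method back to the natural scale for log-space parameters
    scale <- vapply(seq_along(free), function(i) {
      if (free[i] %in% .log_params) p_hat[[free[i]]] else 1
    }, numeric(1))
    cov <- diag(scale) %*% cov_theta %*% diag(scale)
    dimnames(cov) <- list(free, free)
    se <- sqrt(pmax(diag(cov), 0))
    names(se) <- free
  }
  # fitted amplitudes are estimates and may legitimately stray slightly
  # negative under noise, so bypass the constructor's sign checks
  params <- structure(p_hat[.param_names], class = "kinetic_params")
  structure(list(params = params, se = se, cov = cov, redchi2 = redchi2,
                 converged = converged, info = res$info,
                 message = res$message, niter = res$niter, free = free),
            class = "transient_fit")
}

#' @export
print.transient_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat("transient_fit: NOT converged -", x$message, "\n")
    return(invisible(x))
  }
  fmt <- function(nm, scale, unit) {
    if (nm %in% x$free) {
      sprintf("%.4g +/- %.2g %s", x$params[[nm]] * scale,
              x$se[[nm]] * scale, unit)
    } else sprintf("%.4g %s (fixed)", x$params[[nm]] * scale, unit)
  }
  cat("Sequential-model fit (", paste(x$free, collapse = ", "), " free)\n",
      sep = "")
  cat("  tau_fast:", fmt("tau_fast", 1e15, "fs"), "\n")
  cat("  tau_slow:", fmt("tau_slow", 1e12, "ps"), "\n")
  cat(sprintf("  reduced chi-square: %.3f\n", x$redchi2))
  invisible(x)
}

#' Default pump-probe delay grid
#'
#' Mixed linear/logarithmic delay grid: dense linear sampling through time
#' zero to resolve the sub-ps component, then logarithmic coverage of the
#' slow decay.
#'
#' @param n Total number of delays.
#' @param t_min,t_max Range in seconds (default -0.5 ps to 400 ps).
#' @param n_early Number of linear points through time zero.
#' @return Strictly increasing delays in seconds.
#' @export
pump_probe_delays <- function(n = 60, t_min = -0.5e-12, t_max = 400e-12,
                              n_early = 20) {
  early <- seq(t_min, 0.55e-12, length.out = n_early)
  late <- 10^seq(log10(0.7e-12), log10(t_max), length.out = n - n_early)
  sort(unique(c(early, late)))
}
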