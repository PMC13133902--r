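#' Laser power-dependence series
#'
#' Neutral/fragment yield as a function of laser pulse energy at one
#' wavelength, used to determine the number of photons in the activation
#' step.
#'
#' @param pulse_energy Pulse energies (arbitrary units), > 0, at least 3
#'   distinct values.
#' @param yield Yields (counts), >= 0.
#' @param sigma Optional per-point uncertainties.
#' @param wavelength_nm Wavelength tag.
#' @return Data frame of class `power_series`.
#' @export
power_series <- function(pulse_energy, yield, sigma = NULL,
                         wavelength_nm = NA_real_) {
  if (any(pulse_energy <= 0)) stop("pulse energies must be positive", call. = FALSE)
  if (length(unique(pulse_energy)) < 3) {
    stop("need at least 3 distinct pulse energies", call. = FALSE)
  }
  if (length(yield) != length(pulse_energy)) stop("length mismatch", call. = FALSE)
  if (is.null(sigma)) sigma <- rep(NA_real_, length(yield))
  out <- data.frame(pulse_energy = pulse_energy, yield = yield, sigma = sigma)
  attr(out, "wavelength_nm") <- wavelength_nm
  class(out) <- c("power_series", class(out))
  out
}

#' Fit the photon-order exponent of a power series
#'
#' Weighted linear regression of `log(yield)` on `log(pulse_energy)`: for a
#' yield `y = c P^n` the slope is the photon order `n`.  Non-positive yields
#' cannot enter the log fit and are dropped with a message.
#'
#' @param series A [power_series()].
#' @return List of class `power_fit`: `exponent` (`n`), `se` (standard
#'   error), `n_dropped`, `fit` (the underlying `lm`).
#' @export
#' @examples
#' s <- power_series(1:6, 3 * (1:6)^2)
#' fit_power_exponent(s)$exponent  # exactly 2
fit_power_exponent <- function(series) {
  stopifnot(inherits(series, "power_series"))
  use <- series$yield > 0
  n_dropped <- sum(!use)
  if (n_dropped > 0) {
    message(sprintf("dropping %d non-positive yield(s) from the log-log fit",
                    n_dropped))
  }
  s <- series[use, , drop = FALSE]
  if (length(unique(s$pulse_energy)) < 3) {
    stop("fewer than 3 usable points for the power-law fit", call. = FALSE)
  }
  x <- log(s$pulse_energy); y <- log(s$yield)
  w <- if (all(is.na(s$sigma))) NULL else (s$yield / s$sigma)^2
  fit <- if (is.null(w)) stats::lm(y ~ x) else stats::lm(y ~ x, weights = w)
  # noiseless power laws are a legitimate input; summary.lm warns about the
  # resulting perfect fit, which is exactly what the caller asked to verify
  co <- withCallingHandlers(
    summary(fit)$coefficients,
    warning = function(w_) {
      if (grepl("essentially perfect fit", conditionMessage(w_)))
        invokeRestart("muffleWarning")
    })
  structure(list(exponent = unname(co["x", "Estimate"]),
                 se = unname(co["x", "Std. Error"]),
                 n_dropped = n_dropped, fit = fit),
            class = "power_fit")
}

#' @export
print.power_fit <- function(x, ...) {
  cat(sprintf("power-law exponent n = %.3f +/- %.3f (%s)\n", x$exponent,
              x$se, classify_photon_order(x$exponent, x$se)))
  invisible(x)
}

#' Classify the photon order of a fitted exponent
#'
#' An exponent is called one- or two-photon when it lies within
#' `max(2 * sigma_n, band)` of the corresponding integer; everything else
#' (including higher orders) is `"ambiguous"`.  The floor `band` prevents
#' over-claiming from sparse series with tiny formal errors.
#'
#' @param n Fitted exponent.
#' @param sigma_n Its standard error, >= 0.
#' @param band Minimum half-width of the acceptance band (default 0.15).
#' @return `"one_photon"`, `"two_photon"` or `"ambiguous"`.
#' @export
classify_photon_order <- function(n, sigma_n, band = 0.15) {
  if (sigma_n < 0) stop("sigma_n must be >= 0", call. = FALSE)
  m <- round(n)
  if (m %in% c(1, 2) && abs(n - m) <= max(2 * sigma_n, band)) {
    c("one_photon", "two_photon")[m]
  } else {
    "ambiguous"
  }
}

#' Normalise yields by the laser-power dependence
#'
#' Divides yields by `pulse_energy^n` so that action spectra recorded at
#' varying pulse energy become comparable; a series obeying `y = c P^n`
#' normalises to the constant `c`.
#'
#' @param yield Yields.
#' @param pulse_energy Pulse energies, > 0.
#' @param n Photon order.
#' @return Normalised yields.
#' @export
normalize_by_power <- function(yield, pulse_energy, n) {
  if (any(pulse_energy <= 0)) stop("pulse energies must be positive", call. = FALSE)
  yield / pulse_energy^n
}
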