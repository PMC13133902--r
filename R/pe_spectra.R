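#' Photodetachment channel specification for spectrum simulation
#'
#' Describes one additive component of the simulated 2D photoelectron
#' spectrum.  Ridge channels place a Gaussian in eKE at the channel's
#' energetic position for every photon energy where the channel is open:
#' `direct_d0` at `hv - VDE(D0)`, `direct_d1n` at `hv - VDE(D1n)`,
#' `two_photon_s1` at `AEE(S1) + hv - VDE(D0)`.  `low_eke` adds an
#' exponential tail `exp(-eKE / decay)` of statistical low-energy electrons,
#' and `s3_broadening` adds a wider ridge at the direct position inside the
#' S3 shape-resonance photon-energy window.
#'
#' @param kind One of `"direct_d0"`, `"direct_d1n"`, `"two_photon_s1"`,
#'   `"low_eke"`, `"s3_broadening"`.
#' @param amplitude Relative amplitude, >= 0.
#' @param width Gaussian eKE width (standard deviation), eV, > 0.
#' @param decay Decay constant of the low-eKE tail, eV.
#' @param hv_window Photon-energy window for `s3_broadening`, eV.
#' @param extra_width Additional width for `s3_broadening`, eV.
#' @return Object of class `channel_spec`.
#' @export
channel_spec <- function(kind = c("direct_d0", "direct_d1n", "two_photon_s1",
                                  "low_eke", "s3_broadening"),
                         amplitude = 1, width = 0.15, decay = 0.2,
                         hv_window = c(3.6, 3.9), extra_width = 0.15) {
  kind <- match.arg(kind)
  if (width <= 0 || extra_width <= 0 || decay <= 0) {
    stop("widths and decay must be > 0", call. = FALSE)
  }
  if (amplitude < 0) stop("amplitude must be >= 0", call. = FALSE)
  structure(list(kind = kind, amplitude = amplitude, width = width,
                 decay = decay, hv_window = hv_window,
                 extra_width = extra_width), class = "channel_spec")
}

.channel_center <- function(ch, hv, diagram, provenance) {
  vde_d0 <- function() detachment_threshold(diagram, "vde_d0", provenance)
  switch(ch$kind,
         direct_d0 = ,
         s3_broadening = hv - vde_d0(),
         direct_d1n = hv - detachment_threshold(diagram, "vde_d1n", provenance),
         two_photon_s1 = {
           aee <- get_state(diagram, "S1")$adiabatic_eV
           aee + hv - vde_d0()
         },
         NA_real_)
}

#' Forward-simulate a 2D photoelectron spectrum
#'
#' Builds the intensity matrix over (photon energy, electron kinetic energy)
#' from a level diagram and a list of channel specifications, the synthetic
#' twin of a nanosecond-laser 2D photoelectron map with its five
#' characteristic regions.  Closed channels (non-positive eKE position)
#' contribute nothing.  The output is normalised to unit maximum since
#' absolute electron counts are instrument-dependent.
#'
#' @param diagram A [level_diagram()].
#' @param channels List of [channel_spec()] objects.
#' @param hv Photon-energy axis, eV, strictly increasing.
#' @param eke eKE axis, eV, strictly increasing.
#' @param provenance Threshold provenance passed to
#'   [detachment_threshold()].
#' @param keep_components Keep the per-channel matrices (needed to score a
#'   classifier against the generating channel)?
#' @return Object of class `pe_spectrum_2d`: `hv`, `eke`, `intensity`
#'   (matrix, rows = photon energies) and optionally `components`.
#' @export
simulate_pe2d <- function(diagram, channels, hv, eke, provenance = NULL,
                          keep_components = TRUE) {
  stopifnot(inherits(diagram, "level_diagram"))
  if (any(diff(hv) <= 0) || any(diff(eke) <= 0)) {
    stop("axes must be strictly increasing", call. = FALSE)
  }
  if (inherits(channels, "channel_spec")) channels <- list(channels)
  total <- matrix(0, length(hv), length(eke))
  comps <- list()
  for (ch in channels) {
    m <- matrix(0, length(hv), length(eke))
    if (ch$kind == "low_eke") {
      m <- ch$amplitude * outer(rep(1, length(hv)), exp(-eke / ch$decay))
    } else {
      centers <- .channel_center(ch, hv, diagram, provenance)
      w <- if (ch$kind == "s3_broadening") ch$width + ch$extra_width else ch$width
      rows <- which(centers > 0)
      if (ch$kind == "s3_broadening") {
        rows <- intersect(rows, which(hv >= ch$hv_window[1] &
                                        hv <= ch$hv_window[2]))
      }
      for (i in rows) {
        m[i, ] <- ch$amplitude * exp(-(eke - centers[i])^2 / (2 * w^2))
      }
    }
    total <- total + m
    comps[[ch$kind]] <- m
  }
  mx <- max(total)
  if (mx > 0) {
    total <- total / mx
    comps <- lapply(comps, function(m) m / mx)
  }
  structure(list(hv = hv, eke = eke, intensity = total,
                 components = if (keep_components) comps else NULL),
            class = "pe_spectrum_2d")
}

#' @export
print.pe_spectrum_2d <- function(x, ...) {
  cat(sprintf("pe_spectrum_2d: %d photon energies (%.2f-%.2f eV) x %d eKE bins (%.2f-%.2f eV)\n",
              length(x$hv), min(x$hv), max(x$hv), length(x$eke),
              min(x$eke), max(x$eke)))
  invisible(x)
}

#' 1D spectral cut at fixed photon energy
#'
#' Extracts the column of the 2D spectrum nearest to the requested photon
#' energy.
#'
#' @param spec A `pe_spectrum_2d`.
#' @param hv Photon energy (eV), inside the axis range.
#' @return Data frame of class `pe_cut` with columns `eke`, `intensity`;
#'   attribute `hv` records the actual axis value used.
#' @export
spectral_cut <- function(spec, hv) {
  stopifnot(inherits(spec, "pe_spectrum_2d"))
  if (hv < min(spec$hv) || hv > max(spec$hv)) {
    stop(sprintf("photon energy %.3f eV outside the axis range [%.3f, %.3f]",
                 hv, min(spec$hv), max(spec$hv)), call. = FALSE)
  }
  i <- which.min(abs(spec$hv - hv))
  out <- data.frame(eke = spec$eke, intensity = spec$intensity[i, ])
  attr(out, "hv") <- spec$hv[i]
  class(out) <- c("pe_cut", class(out))
  out
}

#' Peak electron kinetic energy of a 1D cut
#'
#' Three-point parabolic interpolation around the maximum bin.  Exact ties
#' between separated maxima resolve to the lowest-eKE peak; a maximum at an
#' axis edge is returned without interpolation.
#'
#' @param cut A [spectral_cut()] result, or a data frame with columns `eke`
#'   and `intensity`.
#' @return Peak eKE in eV.
#' @export
peak_eke <- function(cut) {
  y <- cut$intensity; e <- cut$eke
  if (all(y == 0)) stop("empty signal: all-zero spectral cut", call. = FALSE)
  i <- which(y == max(y))[1L]  # ties: lowest eKE (axis is increasing)
  if (i == 1L || i == length(y)) return(e[i])
  denom <- y[i - 1L] - 2 * y[i] + y[i + 1L]
  if (denom == 0) return(e[i])
  delta <- 0.5 * (y[i - 1L] - y[i + 1L]) / denom
  e[i] + delta * (e[i + 1L] - e[i])
}
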