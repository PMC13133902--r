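#' Photon energy / wavelength conversion
#'
#' Converts between photon wavelength (nm) and photon energy (eV) using
#' h*c = 1239.84193 eV nm.  The two functions are exact inverses.
#'
#' @param wavelength_nm Wavelength in nm, > 0.
#' @param energy_eV Photon energy in eV, > 0.
#' @return Energy in eV (`photon_energy`) or wavelength in nm
#'   (`photon_wavelength`).
#' @export
#' @examples
#' photon_energy(800)      # 1.55 eV probe photon
#' photon_wavelength(1.76) # ~704 nm, the vertical S0 -> S1 transition
photon_energy <- function(wavelength_nm) {
  if (any(!is.finite(wavelength_nm)) || any(wavelength_nm <= 0)) {
    stop("wavelength must be positive and finite", call. = FALSE)
  }
  .hc_eV_nm / wavelength_nm
}

#' @rdname photon_energy
#' @export
photon_wavelength <- function(energy_eV) {
  if (any(!is.finite(energy_eV)) || any(energy_eV <= 0)) {
    stop("photon energy must be positive and finite", call. = FALSE)
  }
  .hc_eV_nm / energy_eV
}

# eKE results carry an open/closed flag instead of raising on closed
# channels, so spectra simulation can sweep all channels uniformly.
channel_energy <- function(value) {
  structure(as.numeric(value), open = value > 0, class = "channel_energy")
}

#' Is a photodetachment channel energetically open?
#'
#' @param x A value returned by [eke_direct()] or [eke_from_excited()].
#' @return Logical vector: `TRUE` where the electron kinetic energy is
#'   positive.
#' @export
is_open <- function(x) {
  op <- attr(x, "open")
  if (is.null(op)) as.numeric(x) > 0 else op
}

#' @export
print.channel_energy <- function(x, ...) {
  cat(sprintf("eKE = %s eV [%s]\n", format(as.numeric(x)),
              ifelse(is_open(x), "open", "closed")), sep = "")
  invisible(x)
}

#' Electron kinetic energy for direct photodetachment
#'
#' Direct one-photon detachment `hv + S0 -> D0 + e-` releases electrons with
#' `eKE = hv - VDE`.  A non-positive result marks an energetically closed
#' channel; it is returned flagged (see [is_open()]) rather than raising.
#'
#' @param hv Photon energy in eV, > 0.
#' @param vde Vertical detachment energy in eV, > 0.
#' @return `channel_energy` value (numeric eV with an `open` attribute).
#' @export
#' @examples
#' eke_direct(4.28, 2.63)  # 1.65 eV on the direct ridge
eke_direct <- function(hv, vde) {
  if (any(hv <= 0) || any(vde <= 0)) {
    stop("hv and vde must be positive", call. = FALSE)
  }
  channel_energy(hv - vde)
}

#' Maximum electron kinetic energy for detachment from an excited anion state
#'
#' Detachment out of an excited state born at adiabatic excitation energy
#' `aee_state` gives at most `eKE = AEE + hv - VDE`.  With `aee_state = 0`
#' this reduces to [eke_direct()].
#'
#' @param aee_state Adiabatic excitation energy of the intermediate anion
#'   state (eV, >= 0).
#' @param hv Photon energy in eV.
#' @param vde_neutral Vertical detachment energy to the neutral state (eV).
#' @return `channel_energy` value in eV.
#' @export
#' @examples
#' # two sequential 3.02 eV photons via S1: ~2.0 eV electrons
#' eke_from_excited(1.51, 3.02, 2.54)
#' # 800 nm probe of the trapped S1 state: ~0.5 eV electrons
#' eke_from_excited(1.51, photon_energy(800), 2.54)
eke_from_excited <- function(aee_state, hv, vde_neutral) {
  if (any(aee_state < 0) || any(hv < 0) || any(vde_neutral < 0)) {
    stop("all energies must be >= 0", call. = FALSE)
  }
  channel_energy(aee_state + hv - vde_neutral)
}

#' Excess vibrational energy after internal conversion
#'
#' A pump photon `hv_pump` that populates a state of adiabatic excitation
#' energy `aee_state` leaves `hv_pump - aee_state` of vibrational energy in
#' that state once internal conversion is complete.
#'
#' @param hv_pump Pump photon energy in eV.
#' @param aee_state Adiabatic excitation energy of the populated state (eV).
#' @return Excess vibrational energy in eV.
#' @export
#' @examples
#' excess_vibrational_energy(3.10, 1.51)  # 1.59 eV of heat in S1
excess_vibrational_energy <- function(hv_pump, aee_state) {
  if (any(hv_pump < aee_state)) {
    stop("closed channel: pump photon energy is below the state's adiabatic excitation energy",
         call. = FALSE)
  }
  hv_pump - aee_state
}

#' Electron binding energy from a photoelectron peak
#'
#' @param hv_probe Probe photon energy in eV.
#' @param eke_peak Peak electron kinetic energy in eV, `0 <= eke_peak <= hv`.
#' @return Binding energy `hv - eKE` in eV.
#' @export
#' @examples
#' binding_energy_from_peak(1.55, 0.45)  # ~1.1 eV S1 binding energy
binding_energy_from_peak <- function(hv_probe, eke_peak) {
  if (any(eke_peak < 0) || any(eke_peak > hv_probe)) {
    stop("inconsistent input: need 0 <= eke_peak <= hv_probe", call. = FALSE)
  }
  hv_probe - eke_peak
}

#' Adiabatic excitation energy from photoelectron observables
#'
#' Combining the anion's vertical detachment energy with the vertical
#' electron binding energy of an excited state gives that state's adiabatic
#' excitation energy: `AEE = VDE(D0) - BE`.
#'
#' @param vde_d0 Vertical detachment energy to D0, eV.
#' @param binding_s1 Vertical electron binding energy of the excited state, eV.
#' @return Adiabatic excitation energy in eV.
#' @export
#' @examples
#' aee_from_photoelectron(2.6, 1.1)  # 1.5 eV for the dark S1 state
aee_from_photoelectron <- function(vde_d0, binding_s1) {
  if (any(binding_s1 > vde_d0)) {
    stop("inconsistent input: binding energy exceeds the detachment energy",
         call. = FALSE)
  }
  vde_d0 - binding_s1
}

#' Classify a (photon energy, electron kinetic energy) pixel
#'
#' Assigns a pixel of the 2D photoelectron spectrum to one of the five
#' mechanistic regions: (i) direct detachment to D0, (ii) direct detachment
#' to the excited neutral D1n, (iii) two-photon detachment via the trapped
#' S1 state (eKE above the direct line), (iv) low-energy electrons from
#' statistical emission after internal conversion, and (v) the broadened
#' direct ridge inside the S3 shape-resonance window.  Overlaps are resolved
#' by the fixed priority order iii > i > ii > v > iv; every pixel gets
#' exactly one label (possibly `"unassigned"`).
#'
#' @param hv Photon energy (eV); vectorised together with `eke`.
#' @param eke Electron kinetic energy (eV).
#' @param diagram A [level_diagram()] providing `vde_d0` (and `vde_d1n` for
#'   region ii).
#' @param tol Half-width (eV) of the direct-ridge acceptance band, > 0.
#' @param low_eke_cutoff Upper eKE bound for region iv (eV).
#' @param broadening_tol Ridge half-width used for region v (eV), wider
#'   than `tol`.
#' @param s3_window Photon-energy window (eV) of the S3 shape resonance.
#' @param provenance Which threshold provenance to use (see
#'   [detachment_threshold()]).
#' @return Character vector of labels in
#'   `c("i","ii","iii","iv","v","unassigned")`.
#' @export
classify_channel <- function(hv, eke, diagram, tol = 0.1,
                             low_eke_cutoff = 0.1, broadening_tol = 0.25,
                             s3_window = c(3.6, 3.9), provenance = NULL) {
  if (tol <= 0) stop("tol must be > 0", call. = FALSE)
  vde_d0 <- detachment_threshold(diagram, "vde_d0", provenance)
  vde_d1n <- tryCatch(detachment_threshold(diagram, "vde_d1n", provenance),
                      error = function(e) NA_real_)
  n <- max(length(hv), length(eke))
  hv <- rep_len(hv, n); eke <- rep_len(eke, n)
  direct <- hv - vde_d0
  lab <- rep("unassigned", n)
  is_iv <- eke <= low_eke_cutoff
  lab[is_iv] <- "iv"
  is_v <- hv >= s3_window[1] & hv <= s3_window[2] &
    abs(eke - direct) <= broadening_tol
  lab[is_v] <- "v"
  if (!is.na(vde_d1n)) {
    is_ii <- abs(eke - (hv - vde_d1n)) <= tol
    lab[is_ii] <- "ii"
  }
  is_i <- abs(eke - direct) <= tol
  lab[is_i] <- "i"
  is_iii <- eke > direct + tol
  lab[is_iii] <- "iii"
  lab
}
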