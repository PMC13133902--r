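# Unit conventions used throughout the package:
#   energies in eV, vibrational frequencies in cm^-1, times in seconds,
#   wavelengths in nm, temperatures in K.  CSV I/O uses ps for delays.
.hc_eV_nm <- 1239.84193        # h*c, eV nm
.h_eV_s <- 4.135667696e-15     # Planck constant, eV s
.kB_eV_K <- 8.617333e-5        # Boltzmann constant, eV / K
.cm1_per_eV <- 8065.544        # wavenumbers per eV

#' Physical constants used by darktrap
#'
#' Returns the fixed physical constants the package computes with, mainly so
#' that scripts and tests can reuse exactly the same values.
#'
#' @return Named numeric vector with elements `hc_eV_nm`, `h_eV_s`,
#'   `kB_eV_K` and `cm1_per_eV`.
#' @export
#' @examples
#' dark_constants()["hc_eV_nm"]
dark_constants <- function() {
  c(hc_eV_nm = .hc_eV_nm, h_eV_s = .h_eV_s,
    kB_eV_K = .kB_eV_K, cm1_per_eV = .cm1_per_eV)
}

# seed-scoped RNG evaluation; leaves the caller's RNG state untouched
.with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}
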