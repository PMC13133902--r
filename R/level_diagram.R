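#' Electronic state level
#'
#' One electronic state of the anion or the neutral radical, with energies
#' referenced to the anion S0 minimum.
#'
#' @param label Short unique identifier, e.g. `"S1"`, `"D0"`, `"D1n"`.
#' @param species `"anion"` or `"neutral"`.
#' @param adiabatic_eV Adiabatic energy (eV) relative to the anion S0
#'   minimum, or `NA` if unknown.
#' @param vertical_eV Vertical energy (eV) at the S0 equilibrium geometry,
#'   or `NA`.
#' @param oscillator_strength Oscillator strength of the transition from S0,
#'   or `NA`.
#' @param provenance `"calculated"` or `"measured"`.
#' @return A one-row data frame of class `state_level`.
#' @export
state_level <- function(label, species = c("anion", "neutral"),
                        adiabatic_eV = NA_real_, vertical_eV = NA_real_,
                        oscillator_strength = NA_real_,
                        provenance = "calculated") {
  species <- match.arg(species)
  if (!is.na(adiabatic_eV) && !is.na(vertical_eV) &&
      adiabatic_eV > vertical_eV + 1e-9) {
    stop(sprintf("state '%s': adiabatic energy (%.3f) exceeds vertical energy (%.3f)",
                 label, adiabatic_eV, vertical_eV), call. = FALSE)
  }
  if (!is.na(oscillator_strength) && oscillator_strength < 0) {
    stop(sprintf("state '%s': oscillator strength must be >= 0", label),
         call. = FALSE)
  }
  out <- data.frame(label = as.character(label), species = species,
                    adiabatic_eV = adiabatic_eV, vertical_eV = vertical_eV,
                    oscillator_strength = oscillator_strength,
                    provenance = provenance, stringsAsFactors = FALSE)
  class(out) <- c("state_level", class(out))
  out
}

#' Electronic level diagram of an anion and its neutral
#'
#' Collects the electronic states together with the photodetachment
#' thresholds (vertical and adiabatic detachment energies).  Threshold values
#' carry a provenance tag (`measured` or `calculated`) because experiments
#' and calculations are routinely mixed when assigning photoelectron spectra.
#'
#' @param states Data frame of states, typically built by rbinding
#'   [state_level()] rows.
#' @param thresholds Named list; each element is a named numeric vector whose
#'   names are provenance tags, e.g.
#'   `list(vde_d0 = c(measured = 2.63, calculated = 2.54))`.  Recognised
#'   names are `vde_d0`, `ade_d0` and `vde_d1n`.
#' @param meci Optional named numeric vector of minimum-energy conical
#'   intersection heights (eV) relative to the S1 minimum.
#' @return Object of class `level_diagram`.
#' @seealso [read_level_diagram()] for the packaged JSON format.
#' @export
level_diagram <- function(states, thresholds, meci = NULL) {
  stopifnot(is.data.frame(states))
  if (anyDuplicated(states$label)) {
    stop("state labels must be unique", call. = FALSE)
  }
  if (!"vde_d0" %in% names(thresholds) || !"ade_d0" %in% names(thresholds)) {
    stop("thresholds must contain at least 'vde_d0' and 'ade_d0'",
         call. = FALSE)
  }
  th <- lapply(thresholds, function(x) {
    x <- unlist(x)
    if (any(x <= 0)) stop("all detachment thresholds must be > 0", call. = FALSE)
    x
  })
  if (max(th$ade_d0) > min(th$vde_d0) + 1e-9) {
    stop("ade_d0 must not exceed vde_d0", call. = FALSE)
  }
  s0 <- states$adiabatic_eV[states$label == "S0"]
  if (length(s0) == 1L && !is.na(s0) && abs(s0) > 1e-12) {
    stop("S0 must have adiabatic energy 0 (it defines the energy origin)",
         call. = FALSE)
  }
  structure(list(states = states, thresholds = th, meci = meci),
            class = "level_diagram")
}

#' @export
print.level_diagram <- function(x, ...) {
  cat("Electronic level diagram:", nrow(x$states), "states\n")
  print(x$states, row.names = FALSE)
  cat("Detachment thresholds (eV):\n")
  for (nm in names(x$thresholds)) {
    v <- x$thresholds[[nm]]
    cat(sprintf("  %-8s %s\n", nm,
                paste(sprintf("%s=%.2f", names(v), v), collapse = ", ")))
  }
  invisible(x)
}

#' Look up a state by label
#'
#' @param diagram A [level_diagram()].
#' @param label State label.
#' @return The matching one-row state data frame; errors if absent.
#' @export
get_state <- function(diagram, label) {
  stopifnot(inherits(diagram, "level_diagram"))
  i <- match(label, diagram$states$label)
  if (is.na(i)) {
    stop(sprintf("state '%s' not found in level diagram", label),
         call. = FALSE)
  }
  diagram$states[i, , drop = FALSE]
}

#' Look up a detachment threshold
#'
#' @param diagram A [level_diagram()].
#' @param name One of `"vde_d0"`, `"ade_d0"`, `"vde_d1n"`.
#' @param provenance `"measured"`, `"calculated"`, or `NULL` to take the
#'   measured value when present and otherwise the calculated one.
#' @return Threshold energy in eV.
#' @export
detachment_threshold <- function(diagram, name, provenance = NULL) {
  stopifnot(inherits(diagram, "level_diagram"))
  v <- diagram$thresholds[[name]]
  if (is.null(v)) {
    stop(sprintf("threshold '%s' not present in level diagram", name),
         call. = FALSE)
  }
  if (is.null(provenance)) {
    for (p in c("measured", "calculated")) if (p %in% names(v)) return(unname(v[[p]]))
    return(unname(v[[1L]]))
  }
  if (!provenance %in% names(v)) {
    stop(sprintf("threshold '%s' has no '%s' value", name, provenance),
         call. = FALSE)
  }
  unname(v[[provenance]])
}

#' Gap between the D1n and D0 detachment thresholds
#'
#' @inheritParams detachment_threshold
#' @return `vde_d1n - vde_d0` in eV.
#' @export
d1n_gap <- function(diagram, provenance = "calculated") {
  detachment_threshold(diagram, "vde_d1n", provenance) -
    detachment_threshold(diagram, "vde_d0", provenance)
}

.parse_valued <- function(x, field, path) {
  # accepts {value_eV, provenance} or a list of such objects
  if (!is.null(x$value_eV)) x <- list(x)
  vals <- vapply(x, function(e) {
    if (is.null(e$value_eV)) {
      stop(sprintf("level diagram file '%s': field '%s' entry lacks 'value_eV'",
                   path, field), call. = FALSE)
    }
    as.numeric(e$value_eV)
  }, numeric(1))
  names(vals) <- vapply(x, function(e) {
    if (is.null(e$provenance)) "calculated" else as.character(e$provenance)
  }, character(1))
  vals
}

#' Read a level diagram from JSON
#'
#' Reads the JSON level-diagram format: top-level keys `states` (array of
#' state objects), `vde_d0`, `ade_d0`, optionally `vde_d1n` and `meci`.
#' Energy-valued fields are objects `{"value_eV": ..., "provenance": ...}`
#' or arrays of such objects when both a measured and a calculated value
#' exist.  A fixture for the meta-HBDI anion ships with the package:
#' `system.file("extdata", "meta_hbdi_levels.json", package = "darktrap")`.
#'
#' @param path Path to the JSON file.
#' @return A [level_diagram()].
#' @export
#' @examples
#' d <- read_level_diagram(system.file("extdata", "meta_hbdi_levels.json",
#'                                     package = "darktrap"))
#' detachment_threshold(d, "vde_d0", "measured")
read_level_diagram <- function(path) {
  if (!file.exists(path)) stop(sprintf("file '%s' does not exist", path), call. = FALSE)
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (key in c("states", "vde_d0", "ade_d0")) {
    if (is.null(j[[key]])) {
      stop(sprintf("level diagram file '%s' is missing required field '%s'",
                   path, key), call. = FALSE)
    }
  }
  states <- do.call(rbind, lapply(j$states, function(s) {
    if (is.null(s$label)) {
      stop(sprintf("level diagram file '%s': a state entry lacks 'label'", path),
           call. = FALSE)
    }
    num <- function(field) {
      if (is.null(s[[field]])) return(NA_real_)
      v <- s[[field]]
      as.numeric(if (is.list(v)) (if (!is.null(v$value_eV)) v$value_eV else v$value) else v)
    }
    state_level(label = s$label,
                species = if (is.null(s$species)) "anion" else s$species,
                adiabatic_eV = num("adiabatic_eV"),
                vertical_eV = num("vertical_eV"),
                oscillator_strength = num("oscillator_strength"),
                provenance = if (is.null(s$provenance)) "calculated" else s$provenance)
  }))
  thresholds <- list()
  for (key in c("vde_d0", "ade_d0", "vde_d1n")) {
    if (!is.null(j[[key]])) thresholds[[key]] <- .parse_valued(j[[key]], key, path)
  }
  meci <- NULL
  if (!is.null(j$meci)) {
    meci <- vapply(j$meci, function(e) as.numeric(e$value_eV), numeric(1))
    names(meci) <- names(j$meci)
  }
  level_diagram(states, thresholds, meci)
}
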