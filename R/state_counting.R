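#' Harmonic vibrational frequency set
#'
#' @param frequencies Mode frequencies in cm^-1, all > 0.
#' @param role `"minimum"` for a well or `"transition_state"` for the
#'   activated complex (which has one mode fewer: the reaction coordinate).
#' @return Object of class `frequency_set`.
#' @export
frequency_set <- function(frequencies, role = c("minimum", "transition_state")) {
  role <- match.arg(role)
  frequencies <- as.numeric(frequencies)
  if (length(frequencies) == 0) stop("frequency set is empty", call. = FALSE)
  if (any(!is.finite(frequencies)) || any(frequencies <= 0)) {
    stop("all frequencies must be positive and finite", call. = FALSE)
  }
  structure(list(frequencies = sort(frequencies), role = role),
            class = "frequency_set")
}

#' @export
print.frequency_set <- function(x, ...) {
  cat(sprintf("frequency_set (%s): %d modes, %.0f-%.0f cm^-1\n",
              x$role, length(x$frequencies), min(x$frequencies),
              max(x$frequencies)))
  invisible(x)
}

#' Exact harmonic sum and density of states (Beyer-Swinehart direct count)
#'
#' Counts harmonic vibrational states on an energy grid by the
#' Beyer-Swinehart direct-count recursion.  Each mode frequency is rounded
#' to the nearest grid multiple; energies are measured above the zero-point
#' level, so `W(0) = 1` (the vibrational ground state).
#'
#' @param freqs A [frequency_set()] or numeric vector of frequencies (cm^-1).
#' @param emax Upper edge of the energy grid, cm^-1.
#' @param bin Grid bin width, cm^-1 (default 1).
#' @return Object of class `state_count_grid` with elements `bin`,
#'   `energies` (bin lower edges, cm^-1), `counts` (states per bin),
#'   `W` (cumulative sum of states) and `rho` (states per cm^-1).
#' @export
#' @examples
#' g <- count_states(c(1000, 1500), emax = 3100)
#' state_count_W(g, 3100)  # 7 states: enumerate (n1, n2) by hand
count_states <- function(freqs, emax, bin = 1) {
  if (inherits(freqs, "frequency_set")) freqs <- freqs$frequencies
  freqs <- as.numeric(freqs)
  if (length(freqs) == 0) stop("frequency set is empty", call. = FALSE)
  if (any(!is.finite(freqs)) || any(freqs <= 0)) {
    stop("all frequencies must be positive and finite", call. = FALSE)
  }
  if (!(is.finite(emax) && is.finite(bin) && emax >= bin && bin > 0)) {
    stop("need emax >= bin > 0", call. = FALSE)
  }
  n <- as.integer(floor(emax / bin)) + 1L
  r <- as.integer(round(freqs / bin))
  if (any(r < 1L)) {
    stop("bin width too coarse: a mode rounds to zero grid quanta", call. = FALSE)
  }
  counts <- numeric(n)
  counts[1L] <- 1
  # Beyer-Swinehart T[i] <- T[i] + T[i - r]; each residue chain mod r is a
  # running sum, so it vectorises as cumsum along the chain.
  for (ri in r) {
    if (ri >= n) next
    for (j in seq_len(ri)) {
      idx <- seq.int(j, n, by = ri)
      if (length(idx) > 1L) counts[idx] <- cumsum(counts[idx])
    }
  }
  structure(list(bin = bin, energies = (seq_len(n) - 1L) * bin,
                 counts = counts, W = cumsum(counts), rho = counts / bin),
            class = "state_count_grid")
}

.grid_index <- function(grid, e_cm1) {
  i <- floor(e_cm1 / grid$bin + 1e-9) + 1L
  if (any(i > length(grid$W))) {
    stop("energy exceeds the state-count grid; rebuild with a larger emax",
         call. = FALSE)
  }
  i
}

#' Sum of states W(E)
#'
#' @param grid A `state_count_grid` from [count_states()].
#' @param e_cm1 Energy (cm^-1), vectorised.  Negative energies give 0.
#' @return Number of vibrational states with energy `<= e_cm1`.
#' @export
state_count_W <- function(grid, e_cm1) {
  out <- numeric(length(e_cm1))
  pos <- e_cm1 >= 0
  out[pos] <- grid$W[.grid_index(grid, e_cm1[pos])]
  out
}

#' Density of states rho(E)
#'
#' @inheritParams state_count_W
#' @return States per cm^-1 in the bin containing `e_cm1` (0 below zero).
#' @export
state_count_rho <- function(grid, e_cm1) {
  out <- numeric(length(e_cm1))
  pos <- e_cm1 >= 0
  out[pos] <- grid$rho[.grid_index(grid, e_cm1[pos])]
  out
}
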