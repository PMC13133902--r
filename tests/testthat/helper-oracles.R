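# Independent oracles used by the tests.  These deliberately avoid the
# package's own algorithms: state counts come from exhaustive enumeration
# over quantum numbers, kinetics from numeric ODE integration, areas from
# quadrature, and roots from uniroot.

# all harmonic state energies sum(n_i * f_i) <= emax, by exhaustive
# enumeration over quantum numbers (mode-by-mode expansion with pruning)
enum_state_energies <- function(freqs, emax) {
  states <- 0
  for (f in freqs) {
    ladder <- seq(0, emax, by = f)
    states <- as.vector(outer(states, ladder, "+"))
    states <- states[states <= emax + 1e-9]
  }
  sort(states)
}

# number of harmonic states with sum(n_i * f_i) <= E
enum_sum_of_states <- function(freqs, E) {
  if (E < 0) return(0)
  length(enum_state_energies(freqs, E))
}

# number of harmonic states with energy in [lo, hi)
enum_states_in_window <- function(freqs, lo, hi) {
  s <- enum_state_energies(freqs, hi - 1e-9)
  sum(s >= lo - 1e-9)
}

# classical (fully excited) sum of states E^s / (s! prod(f))
classical_sum_of_states <- function(freqs, E) {
  s <- length(freqs)
  E^s / (factorial(s) * prod(freqs))
}

# sequential cascade populations by stiff ODE integration
ode_populations <- function(t_out, tau_fast, tau_slow) {
  rhs <- function(t, y, parms) {
    k1 <- 1 / parms[1]; k2 <- 1 / parms[2]
    list(c(-k1 * y[1], k1 * y[1] - k2 * y[2], k2 * y[2]))
  }
  out <- deSolve::lsoda(c(1, 0, 0), c(0, t_out), rhs,
                        c(tau_fast, tau_slow), rtol = 1e-12, atol = 1e-14)
  unname(out[-1, -1, drop = FALSE])
}

fixture_diagram <- function() {
  read_level_diagram(system.file("extdata", "meta_hbdi_levels.json",
                                 package = "darktrap"))
}

paper_kinetic_params <- function() {
  kinetic_params(tau_fast = 100e-15, tau_slow = 94e-12, amp_s2 = 1,
                 amp_s1 = 0.5, amp_s0 = 1, baseline_prompt = 0.02,
                 baseline_delayed = 0.02, t0 = 0, irf_sigma = 80e-15)
}
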