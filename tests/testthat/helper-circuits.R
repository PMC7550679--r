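# Small circuits built in code for unit tests.

two_unit_chain <- function(w = 0.05, tau = c(10, 20)) {
  units <- data.frame(
    name = c("A", "B"), tau = tau, tonic = c(0, 0), phi = c(30, 30),
    psi = c(0.5, 0.5), polarity = c("excitatory", "excitatory"),
    neuron_class = "pyramidal", stringsAsFactors = FALSE)
  conns <- data.frame(pre = c("CS", "A"), post = c("A", "B"),
                      weight = c(0.03, w), stringsAsFactors = FALSE)
  fear_circuit(units, conns)
}

single_unit <- function(tonic = 0.5, tau = 20, phi = 40, psi = 0.8) {
  units <- data.frame(name = "A", tau = tau, tonic = tonic, phi = phi,
                      psi = psi, polarity = "excitatory",
                      neuron_class = "pyramidal", stringsAsFactors = FALSE)
  conns <- data.frame(pre = "CS", post = "A", weight = 0.02,
                      stringsAsFactors = FALSE)
  fear_circuit(units, conns)
}

# closed-form relaxation of tau*du/dt = -u + D from u0 (no clamping)
relax <- function(t_ms, u0, drive, tau) drive + (u0 - drive) * exp(-t_ms / tau)
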