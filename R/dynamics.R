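#' Leaky-unit membrane update (one Euler step)
#'
#' Advances the remapped membrane potential of a leaky unit by one explicit
#' Euler step of \eqn{\tau \dot U = -U + T + I}, then clamps the result to the
#' admissible potential range \eqn{[0, \pi]}.
#'
#' Potentials are expressed on the remapped scale where the biological range
#' (-70, +30) mV maps linearly onto (0, \eqn{\pi}); see
#' \code{\link{remap_potential}}.  The resting potential is therefore 0 and a
#' unit with zero drive relaxes back to rest.
#'
#' @param u Current potential (remapped units, in \eqn{[0, \pi]}).
#' @param tonic Tonic drive T of the unit (remapped-potential units).
#' @param input_sum Summed synaptic plus external input I (remapped units).
#' @param tau Membrane time constant, ms.  Must be positive.
#' @param dt Integration step, ms.  Must be positive.
#' @return The updated potential, clamped to \eqn{[0, \pi]}.
#' @examples
#' euler_step(0, tonic = 1, input_sum = 2, tau = 10, dt = 10)  # jumps to T + I = 3 -> pi
#' euler_step(0.5, 0.1, 0.2, tau = 7.7, dt = 1)
#' @export
euler_step <- function(u, tonic, input_sum, tau, dt) {
  if (any(tau <= 0)) stop("`tau` must be positive", call. = FALSE)
  if (any(dt <= 0)) stop("`dt` must be positive", call. = FALSE)
  u_new <- u + (dt / tau) * (-u + tonic + input_sum)
  pmin(pi, pmax(0, u_new))
}

#' Summed synaptic input
#'
#' Computes \eqn{I = \sum_i s_i w_i A_i}: the dot product of connection
#' efficacies and presynaptic firing rates, with the sign \eqn{s_i} taken from
#' the presynaptic unit's polarity.  Weights are stored non-negative
#' throughout the package; inhibitory afferents enter the sum with a negative
#' sign.
#'
#' @param weights Numeric vector of non-negative efficacies.
#' @param activations Numeric vector of presynaptic firing rates (Hz), same
#'   length as `weights`.
#' @param signs Numeric vector of +1 (excitatory) / -1 (inhibitory), recycled
#'   from length 1; default +1.
#' @return The summed drive (scalar).
#' @examples
#' summed_input(c(2, 1), c(3, 4), signs = c(1, -1))  # 6 - 4 = 2
#' summed_input(0.7, 10, signs = -1)                 # -7
#' @export
summed_input <- function(weights, activations, signs = 1) {
  if (length(weights) != length(activations))
    stop("`weights` and `activations` must have equal length", call. = FALSE)
  if (length(weights) == 0L) return(0)
  signs <- rep_len(signs, length(weights))
  sum(signs * weights * activations)
}

#' Rate transfer function
#'
#' Maps a remapped membrane potential to a firing rate through
#' \eqn{A = \phi [\tanh(U - \psi)]^+}: a thresholded hyperbolic tangent whose
#' output lies in \eqn{[0, \phi)}.
#'
#' @param u Potential (remapped units).
#' @param psi Firing threshold (remapped units, \eqn{0 \le \psi < \pi}).
#' @param phi Maximum firing rate, Hz.
#' @return Firing rate, Hz.
#' @examples
#' transfer(1.5, psi = 1.5, phi = 40)   # at threshold -> 0
#' transfer(2.5, psi = 1.5, phi = 40)   # 40 * tanh(1)
#' @export
transfer <- function(u, psi, phi) {
  phi * pmax(0, tanh(u - psi))
}

#' Remap a membrane potential from mV to simulation units (and back)
#'
#' The simulation integrates potentials on a remapped scale where the
#' conventional biological range \eqn{[-70, +30]} mV corresponds linearly to
#' \eqn{[0, \pi]}, so that the leak drives units toward 0 rather than toward a
#' negative resting value.  `unmap_potential` is the exact inverse and is used
#' only for reporting PSPs in mV.  Inputs outside the biological range are
#' clamped.
#'
#' @param v_mv Membrane potential in mV.
#' @return `remap_potential`: potential in \eqn{[0, \pi]};
#'   `unmap_potential`: potential in mV.
#' @examples
#' remap_potential(-70)   # 0
#' remap_potential(30)    # pi
#' unmap_potential(pi / 2)  # -20
#' @export
remap_potential <- function(v_mv) {
  v_mv <- pmin(30, pmax(-70, v_mv))
  (v_mv + 70) * pi / 100
}

#' @rdname remap_potential
#' @param u Potential in remapped units (clamped to \eqn{[0, \pi]}).
#' @export
unmap_potential <- function(u) {
  u <- pmin(pi, pmax(0, u))
  u * 100 / pi - 70
}

# mV per remapped-potential unit; used by PSP reporting.
mv_per_u <- 100 / pi
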