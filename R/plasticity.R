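#' Hebbian LTP/LTD weight change
#'
#' Computes the per-step weight change of the thresholded Hebbian rule
#' \eqn{\Delta W = \eta (M - W)(\mathrm{Post} - \phi\sigma)\,\mathrm{Pre}}:
#' potentiation when the postsynaptic rate exceeds the threshold fraction
#' \eqn{\sigma} of its maximum \eqn{\phi}, depression otherwise.  The soft
#' ceiling factor \eqn{(M - W)} makes the weight approach its maximum
#' \eqn{M} only asymptotically.  The caller is responsible for clamping the
#' updated weight to \eqn{[0, M]} (and, for potentiation-only connections,
#' for discarding negative deltas).
#'
#' @param w Current weight (non-negative).
#' @param pre Presynaptic firing rate, Hz (external channels contribute their
#'   drive value directly).
#' @param post Postsynaptic firing rate, Hz.
#' @param eta Learning-rate constant (> 0), per reference step of 10 ms.
#' @param M Weight ceiling (> 0).
#' @param sigma Postsynaptic threshold fraction in \eqn{[0, 1]}.
#' @param phi Postsynaptic maximum firing rate, Hz.
#' @return The (signed) weight change for one reference step.
#' @examples
#' ltp_ltd_delta(w = 1, pre = 1, post = 2, eta = 0.01, M = 3, sigma = 0.025, phi = 40)
#' @export
ltp_ltd_delta <- function(w, pre, post, eta, M, sigma, phi) {
  eta * (M - w) * (post - phi * sigma) * pre
}

#' Endocannabinoid DSI/DSE weight change
#'
#' Computes the per-step multiplicative depression
#' \eqn{\Delta W = -\eta W \,\mathrm{Pre}} of a depolarization-induced
#' suppression (DSI/DSE) connection.  The rule engages only once the
#' postsynaptic unit has been continuously depolarized for `trigger_s`
#' seconds (default 10 s), tracked by
#' \code{\link{update_depolarization_timer}}, and only while the presynaptic
#' element fires.  Because the decay is multiplicative the weight remains
#' strictly positive.
#'
#' @param w Current weight.
#' @param pre Presynaptic firing rate, Hz.
#' @param eta Depression-rate constant (> 0), per reference step of 10 ms.
#' @param timer Accumulated postsynaptic depolarization time, s.
#' @param trigger_s Depolarization time required before the rule engages, s.
#' @return The weight change for one reference step (0 before the trigger).
#' @examples
#' dsi_dse_delta(w = 2, pre = 1, eta = 0.1, timer = 12, trigger_s = 10)  # -0.2
#' dsi_dse_delta(w = 2, pre = 1, eta = 0.1, timer = 9.99, trigger_s = 10)  # 0
#' @export
dsi_dse_delta <- function(w, pre, eta, timer, trigger_s) {
  if (timer < trigger_s) return(0)
  -eta * w * pre
}

#' Track sustained postsynaptic depolarization
#'
#' Advances the per-unit depolarization timer that gates DSI/DSE: the timer
#' accumulates simulated time while the unit's firing rate is at or above the
#' depolarization threshold `theta_dsi * phi`, and resets to zero the moment
#' activity dips below it (continuous-depolarization semantics).  The timer
#' belongs to the postsynaptic cell and is shared by all of its
#' endocannabinoid-sensitive afferents.
#'
#' @param timer Current accumulated time, s.
#' @param post_activation Postsynaptic firing rate, Hz.
#' @param phi Postsynaptic maximum firing rate, Hz.
#' @param dt Integration step, ms.
#' @param theta_dsi Depolarization threshold as a fraction of `phi`
#'   (default 0.2, the unit-active criterion).
#' @return The updated timer, s.
#' @export
update_depolarization_timer <- function(timer, post_activation, phi, dt,
                                        theta_dsi = 0.2) {
  ifelse(post_activation >= theta_dsi * phi, timer + dt / 1000, 0)
}
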