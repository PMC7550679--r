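#' Plasticity-frozen probe CS
#'
#' Presents a single CS with all weight updates frozen, starting from a
#' given network state (typically the end of a session), and returns the
#' peak activation of every unit during the CS.  Freezing separates
#' measurement from learning, so the probe reads out what the circuit has
#' stored without changing it.
#'
#' @param model A \code{\link{fear_circuit}}.
#' @param state State from a previous run (`trace$state`), or `NULL` to
#'   probe the naive circuit.
#' @param cs_s Probe CS duration, s.
#' @param cfg A \code{\link{sim_config}}.
#' @param perturbations Optional perturbations active during the probe.
#' @param lead_s Quiet time before CS onset, s.
#' @param skip_s Initial part of the CS excluded from the measurement
#'   (default 2 s): the readout is the sustained response, not the brief
#'   synaptic-lag transient at stimulus onset.
#' @return Named vector of peak sustained firing rates during the CS (Hz),
#'   with the probe trace in attribute `"trace"`.
#' @export
probe_cs <- function(model, state = NULL, cs_s = 20, cfg = sim_config(),
                     perturbations = NULL, lead_s = 10, skip_s = 2) {
  p <- conditioning_protocol(n_trials = 1, cs_s = cs_s, us_s = 0,
                             iti_s = lead_s, name = "probe")
  tr <- run_protocol(model, p, cfg, perturbations = perturbations,
                     freeze_plasticity = TRUE, init_state = state)
  pk <- peak_activation(tr, c(lead_s + skip_s, lead_s + cs_s))
  attr(pk, "trace") <- tr
  pk
}

#' Peak activations as percent of each unit's maximum rate
#'
#' @param peaks Named vector of firing rates (Hz), as from
#'   \code{\link{probe_cs}}.
#' @param model The circuit the peaks came from.
#' @return Named vector, percent of phi.
#' @export
percent_of_max <- function(peaks, model) {
  phi <- stats::setNames(model$units$phi, model$units$name)
  100 * peaks / phi[names(peaks)]
}

#' Synaptic strength probe (PSP)
#'
#' Measures the postsynaptic potential evoked through one connection by a
#' brief presynaptic stimulation, in the style of a slice experiment: the
#' probed connection is isolated (the postsynaptic unit integrates only its
#' tonic drive plus the probed input, with no clamping, so the deflection is
#' linear in the weight), plasticity is implicitly frozen, and the
#' deflection is reported in mV through the inverse potential remap.
#'
#' The presynaptic drive is calibrated once by bisection so that the evoked
#' peak is just below `ceiling_mv` in the reference condition; the same
#' drive is then reused for any comparison condition, so percentage changes
#' reflect the weight change alone.
#'
#' @param model A \code{\link{fear_circuit}}.
#' @param pre,post Connection endpoints (`pre` may be `"CS"` or `"US"`).
#' @param weights Optional weight table (from a `trace$state$w` via
#'   \code{\link{weights_as_table}} or \code{\link{snapshot_weights}});
#'   default: the model's current weights.
#' @param drive Presynaptic stimulation amplitude; `NULL` to calibrate by
#'   bisection against `ceiling_mv`.
#' @param duration_ms Stimulation duration (default 30 ms).
#' @param ceiling_mv Calibration ceiling for the evoked PSP (default 10 mV).
#' @param cfg A \code{\link{sim_config}} (its `dt_ms` is used).
#' @return List with `psp_mv` (peak deflection), `drive` (stimulation used)
#'   and `weight`.
#' @examples
#' circ <- build_default_circuit()
#' ref <- psp_probe(circ, "CS", "LAp1")
#' @export
psp_probe <- function(model, pre, post, weights = NULL, drive = NULL,
                      duration_ms = 30, ceiling_mv = 10, cfg = sim_config()) {
  net <- compile_circuit(model)
  ci <- match(paste0(pre, "->", post), net$conn_id)
  if (is.na(ci)) stop("no connection ", pre, "->", post, call. = FALSE)
  w <- if (is.null(weights)) net$w[ci] else {
    id <- paste0(pre, "->", post)
    if (!id %in% names(weights)) stop("`weights` lacks ", id, call. = FALSE)
    unname(weights[id])
  }
  pj <- net$post[ci]
  external_pre <- net$pre[ci] > net$n
  pi_ <- if (external_pre) NA_integer_ else net$pre[ci]
  dt <- cfg$dt_ms
  n_on <- max(1L, round(duration_ms / dt))
  n_total <- n_on + max(1L, round(120 / dt))  # follow the decay

  evoke <- function(amp) {
    # pre activation time course under the stimulation
    if (external_pre) {
      a_pre <- c(rep(amp, n_on), rep(0, n_total - n_on))
    } else {
      u_p <- min(pi, max(0, net$tonic[pi_]))
      a_rest <- transfer(u_p, net$psi[pi_], net$phi[pi_])
      a_pre <- numeric(n_total)
      for (t in seq_len(n_total)) {
        inp <- if (t <= n_on) amp else 0
        u_p <- u_p + (dt / net$tau[pi_]) * (-u_p + net$tonic[pi_] + inp)
        u_p <- min(pi, max(0, u_p))
        a_pre[t] <- transfer(u_p, net$psi[pi_], net$phi[pi_])
      }
      a_pre <- a_pre - a_rest  # evoked component only
    }
    # isolated post membrane, linear (no clamps): deflection from rest
    u_d <- 0; peak <- 0
    for (t in seq_len(n_total)) {
      u_d <- u_d + (dt / net$tau[pj]) * (-u_d + net$sign[ci] * w * a_pre[t])
      if (abs(u_d) > abs(peak)) peak <- u_d
    }
    peak
  }
  to_mv <- function(u) u * 100 / pi

  if (is.null(drive)) {
    lo <- 0; hi <- 1
    while (abs(to_mv(evoke(hi))) < ceiling_mv && hi < 1e7) hi <- hi * 2
    if (hi >= 1e7) {
      drive <- hi  # weight too small to ever reach the ceiling
    } else {
      for (k in 1:60) {
        mid <- (lo + hi) / 2
        if (abs(to_mv(evoke(mid))) < ceiling_mv * 0.98) lo <- mid else
          hi <- mid
      }
      drive <- lo
    }
  }
  list(psp_mv = abs(to_mv(evoke(drive))), drive = drive, weight = w)
}

#' Convert an engine weight vector to a named table
#'
#' @param model The circuit.
#' @param w Numeric weight vector in connection order (e.g.
#'   `trace$state$w`).
#' @return Named vector keyed by `"pre->post"`.
#' @export
weights_as_table <- function(model, w) {
  stats::setNames(w, connection_ids(model))
}

#' Classify units as fear / extinction / persistent
#'
#' Applies the activity taxonomy: a unit is *active* when its probe-CS peak
#' reaches `criteria$unit_active_frac` of its maximum rate.  Fear units are
#' active after conditioning and inactive after extinction; extinction
#' units the reverse; persistent units are active after both; all others
#' `none`.
#'
#' @param post_cond,post_ext Named peak-activation vectors (Hz) from
#'   \code{\link{probe_cs}} after conditioning and after extinction.
#' @param model The circuit (for each unit's maximum rate).
#' @param criteria A \code{\link{criteria_config}}.
#' @return Named character vector: `"fear"`, `"extinction"`, `"persistent"`
#'   or `"none"`.
#' @export
classify_units <- function(post_cond, post_ext, model,
                           criteria = criteria_config()) {
  pc <- percent_of_max(post_cond, model) >= 100 * criteria$unit_active_frac
  pe <- percent_of_max(post_ext, model) >= 100 * criteria$unit_active_frac
  out <- ifelse(pc & !pe, "fear",
                ifelse(!pc & pe, "extinction",
                       ifelse(pc & pe, "persistent", "none")))
  stats::setNames(out, names(post_cond))
}
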