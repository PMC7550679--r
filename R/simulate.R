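#' Simulation configuration
#'
#' @param dt_ms Euler integration step, ms (default 10; the dynamics are
#'   stable and dt-robust because leaky units are low-pass filters).
#' @param settle_s Pre-protocol relaxation so every unit starts at its tonic
#'   fixed point; defaults to 5x the largest membrane time constant.
#' @param record_every Record every k-th step (1 = full resolution).
#' @param seed Integer, reserved for reproducibility bookkeeping; the core
#'   dynamics are fully deterministic.
#' @return A `sim_config` list.
#' @export
sim_config <- function(dt_ms = 10, settle_s = NULL, record_every = 1L,
                       seed = 1L) {
  if (dt_ms <= 0) stop("`dt_ms` must be positive", call. = FALSE)
  if (!is.null(settle_s) && settle_s < 0)
    stop("`settle_s` must be >= 0", call. = FALSE)
  structure(list(dt_ms = dt_ms, settle_s = settle_s,
                 record_every = as.integer(record_every),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Run a stimulus protocol through the circuit
#'
#' Integrates the full network over a protocol: the circuit is first settled
#' at its tonic fixed point, then CS/US epochs are applied while all three
#' plasticity rules operate at every step.  Transient (DSI/DSE) weights are
#' returned to their pre-protocol values at every session boundary.
#' Perturbations (lesions, clamps, weight overrides, plasticity blockades)
#' are applied within their time windows.
#'
#' @param model A \code{\link{fear_circuit}}.
#' @param protocol A `fear_protocol`.
#' @param cfg A \code{\link{sim_config}}.
#' @param perturbations A `fear_perturbation` or list of them (optional).
#' @param freeze_plasticity Disable all weight updates (used for probe
#'   measurements).
#' @param init_state Optional state (`u`, `w`, `timer`, `w_ref`) from a
#'   previous run's `$state`, to continue a simulation.
#' @param record Units/weights are always recorded at `cfg$record_every`
#'   resolution.
#' @return A `fear_trace`: list with `time_s`, `A` (steps x units firing-rate
#'   matrix, Hz), `W` (steps x connections weight matrix), `protocol`,
#'   `state` (final potentials, weights, timers), and `model`.
#' @examples
#' circ <- build_default_circuit()
#' tr <- run_protocol(circ, conditioning_protocol(n_trials = 1),
#'                    sim_config(record_every = 10))
#' @export
run_protocol <- function(model, protocol, cfg = sim_config(),
                         perturbations = NULL, freeze_plasticity = FALSE,
                         init_state = NULL, record = "all") {
  stopifnot(inherits(model, "fear_circuit"),
            inherits(protocol, "fear_protocol"))
  net <- compile_circuit(model)
  dt <- cfg$dt_ms
  settle_s <- if (is.null(cfg$settle_s)) 5 * max(net$tau) / 1000 else
    cfg$settle_s
  amps <- epoch_amplitudes(protocol, dt, settle_s)
  settle_steps <- amps$steps - ceiling(protocol$duration_s * 1000 / dt)

  if (is.null(init_state)) {
    u0 <- pmin(pi, pmax(0, net$tonic))
    w0 <- net$w
    timer0 <- numeric(net$n)
    w_ref <- net$w_init
  } else {
    u0 <- init_state$u; w0 <- init_state$w
    timer0 <- init_state$timer; w_ref <- init_state$w_ref
  }

  reset_steps <- settle_steps +
    as.integer(floor(protocol$session_boundaries * 1000 / dt)) + 1L
  pc <- compile_perturbations(perturbations, net, model, dt, settle_steps,
                              amps$steps)

  res <- sim_core_cpp(net, amps$cs, amps$us, dt,
                      u0, w0, timer0, w_ref,
                      as.integer(reset_steps),
                      isTRUE(freeze_plasticity),
                      as.integer(pc$uc$unit), as.integer(pc$uc$start),
                      as.integer(pc$uc$end), as.integer(pc$uc$mode),
                      as.numeric(pc$uc$value),
                      as.integer(pc$co$conn), as.integer(pc$co$start),
                      as.integer(pc$co$end), as.integer(pc$co$mode),
                      as.numeric(pc$co$value),
                      as.integer(pc$pb$conn), as.integer(pc$pb$start),
                      as.integer(pc$pb$end),
                      cfg$record_every)
  A <- res$A; colnames(A) <- net$names
  W <- res$W; colnames(W) <- net$conn_id
  structure(list(
    time_s = res$time_s - settle_s,
    A = A, W = W,
    protocol = protocol, dt_ms = dt,
    state = list(u = res$u_final, w = res$w_final, timer = res$timer_final,
                 w_ref = w_ref),
    model = model), class = "fear_trace")
}

#' @export
print.fear_trace <- function(x, ...) {
  cat("<fear_trace> ", x$protocol$name, ": ", nrow(x$A), " samples over ",
      round(max(x$time_s), 1), " s, ", ncol(x$A), " units (dt = ", x$dt_ms,
      " ms)\n", sep = "")
  invisible(x)
}

#' @export
summary.fear_trace <- function(object, ...) {
  pk <- apply(object$A, 2, max)
  cat("<fear_trace> peak activations (Hz):\n")
  print(round(pk, 2))
  invisible(pk)
}

#' Peak activations within a time window
#'
#' @param trace A `fear_trace`.
#' @param window `c(start_s, end_s)` in protocol time.
#' @param units Unit names (default all).
#' @return Named vector of peak firing rates, Hz.
#' @export
peak_activation <- function(trace, window, units = colnames(trace$A)) {
  sel <- trace$time_s >= window[1] & trace$time_s <= window[2]
  if (!any(sel)) stop("empty window", call. = FALSE)
  apply(trace$A[sel, units, drop = FALSE], 2, max)
}

#' Pure-R synchronous network step (reference implementation)
#'
#' Advances every unit by one step using \code{\link{summed_input}},
#' \code{\link{euler_step}} and \code{\link{transfer}} with the synchronous
#' update order of the main engine (inputs from previous activations).  Used
#' as the independent cross-check of the compiled integrator and for
#' single-step reasoning; plasticity and perturbations are not applied.
#'
#' @param states List with `u` and `a` vectors (one entry per unit).
#' @param model A `fear_circuit`.
#' @param external Named numeric: external drive per unit and/or `CS`/`US`
#'   channel amplitudes.
#' @param cfg A `sim_config`.
#' @return Updated `states` list.
#' @export
network_step <- function(states, model, external = c(CS = 0, US = 0),
                         cfg = sim_config()) {
  net <- compile_circuit(model)
  bad <- setdiff(names(external), c(net$names, "CS", "US"))
  if (length(bad))
    stop("unknown unit in `external`: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (length(states$u) != net$n)
    stop("`states` must cover every unit", call. = FALSE)
  cs <- if ("CS" %in% names(external)) external[["CS"]] else 0
  us <- if ("US" %in% names(external)) external[["US"]] else 0
  pre_act <- c(states$a, cs, us)
  drive <- numeric(net$n)
  for (j in seq_len(net$n)) {
    sel <- net$post == j
    drive[j] <- summed_input(net$w[sel], pre_act[net$pre[sel]],
                             net$sign[sel])
    if (net$names[j] %in% names(external))
      drive[j] <- drive[j] + external[[net$names[j]]]
  }
  u_new <- euler_step(states$u, net$tonic, drive, net$tau, cfg$dt_ms)
  list(u = u_new, a = transfer(u_new, net$psi, net$phi))
}
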