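#' Stimulus protocols for conditioning, extinction and reinstatement
#'
#' `conditioning_protocol` builds the cued fear-conditioning schedule:
#' `n_trials` CS presentations of `cs_s` seconds, each paired with a US that
#' overlaps the final `us_s` seconds of its CS.  `extinction_protocol` builds
#' a session of `n_cs` unreinforced CS presentations.
#' `reinstatement_protocol` builds the sequence CS (20 s), unpaired US
#' (0.5 s), CS (20 s).  `chain_protocols` concatenates sessions, inserting a
#' gap and (by default) a session boundary at each junction; at every
#' boundary the weights modified by the transient DSI/DSE rules are returned
#' to their pre-protocol values.
#'
#' The inter-trial interval (40 s by default) is long relative to every
#' membrane time constant, so all activations return to baseline between
#' stimuli.
#'
#' @param n_trials,n_cs Number of CS presentations.
#' @param cs_s,us_s CS and US durations, s.
#' @param iti_s Inter-trial interval (stimulus offset to next onset), s.
#' @param cs_amp,us_amp Channel drive while on (default 100).
#' @param name Protocol label.
#' @return A `fear_protocol`: list with `name`, `epochs` (data frame with
#'   `t_start`, `duration`, `channel`, `amplitude`), `duration_s` and
#'   `session_boundaries` (times at which transient weights reset).
#' @examples
#' p <- conditioning_protocol()
#' full <- chain_protocols(p, extinction_protocol(), extinction_protocol(),
#'                         reinstatement_protocol())
#' @export
conditioning_protocol <- function(n_trials = 3, cs_s = 20, us_s = 0.5,
                                  iti_s = 40, cs_amp = 100, us_amp = 100,
                                  name = "conditioning") {
  if (us_s > cs_s) stop("`us_s` must not exceed `cs_s`", call. = FALSE)
  ep <- NULL
  t <- iti_s
  for (i in seq_len(n_trials)) {
    ep <- rbind(ep, data.frame(t_start = t, duration = cs_s, channel = "CS",
                               amplitude = cs_amp))
    if (us_s > 0)
      ep <- rbind(ep, data.frame(t_start = t + cs_s - us_s, duration = us_s,
                                 channel = "US", amplitude = us_amp))
    t <- t + cs_s + iti_s
  }
  if (is.null(ep))
    ep <- data.frame(t_start = numeric(0), duration = numeric(0),
                     channel = character(0), amplitude = numeric(0))
  new_protocol(name, ep, duration_s = t)
}

#' @rdname conditioning_protocol
#' @export
extinction_protocol <- function(n_cs = 20, cs_s = 20, iti_s = 40,
                                cs_amp = 100, name = "extinction") {
  conditioning_protocol(n_trials = n_cs, cs_s = cs_s, us_s = 0,
                        iti_s = iti_s, cs_amp = cs_amp, name = name)
}

#' @rdname conditioning_protocol
#' @export
reinstatement_protocol <- function(cs_s = 20, us_s = 0.5, iti_s = 40,
                                   cs_amp = 100, us_amp = 100,
                                   name = "reinstatement") {
  ep <- data.frame(
    t_start = c(iti_s, iti_s + cs_s + iti_s,
                iti_s + cs_s + iti_s + us_s + iti_s),
    duration = c(cs_s, us_s, cs_s),
    channel = c("CS", "US", "CS"),
    amplitude = c(cs_amp, us_amp, cs_amp))
  new_protocol(name, ep,
               duration_s = iti_s + cs_s + iti_s + us_s + iti_s + cs_s + iti_s)
}

#' @rdname conditioning_protocol
#' @param ... `fear_protocol` objects to concatenate, in order.
#' @param gap_s Silent gap inserted between consecutive sessions, s.
#' @param boundaries Insert a transient-weight reset at each junction?
#' @export
chain_protocols <- function(..., gap_s = 60, boundaries = TRUE) {
  ps <- list(...)
  stopifnot(length(ps) > 0, all(vapply(ps, inherits, TRUE, "fear_protocol")))
  ep <- NULL; bnd <- numeric(0); t0 <- 0; nm <- character(0)
  seg <- NULL
  for (i in seq_along(ps)) {
    p <- ps[[i]]
    if (i > 1) {
      t0 <- t0 + gap_s
      if (boundaries) bnd <- c(bnd, t0)
    }
    e <- p$epochs
    if (nrow(e)) {
      e$t_start <- e$t_start + t0
      ep <- rbind(ep, e)
    }
    seg <- rbind(seg, data.frame(name = p$name, t_start = t0,
                                 t_end = t0 + p$duration_s))
    bnd <- c(bnd, t0 + p$session_boundaries)
    nm <- c(nm, p$name)
    t0 <- t0 + p$duration_s
  }
  out <- new_protocol(paste(nm, collapse = "+"), ep, duration_s = t0,
                      session_boundaries = sort(unique(bnd)))
  out$segments <- seg
  out
}

new_protocol <- function(name, epochs, duration_s,
                         session_boundaries = numeric(0)) {
  epochs <- epochs[order(epochs$t_start), , drop = FALSE]
  rownames(epochs) <- NULL
  for (ch in c("CS", "US")) {
    e <- epochs[epochs$channel == ch, , drop = FALSE]
    if (nrow(e) > 1 &&
        any(e$t_start[-1] < (e$t_start + e$duration)[-nrow(e)] - 1e-9))
      stop("overlapping ", ch, " epochs", call. = FALSE)
  }
  if (nrow(epochs) && any(epochs$duration <= 0))
    stop("epoch durations must be positive", call. = FALSE)
  if (nrow(epochs) && any(epochs$amplitude < 0))
    stop("epoch amplitudes must be >= 0", call. = FALSE)
  structure(list(name = name, epochs = epochs, duration_s = duration_s,
                 session_boundaries = sort(session_boundaries)),
            class = "fear_protocol")
}

#' @export
print.fear_protocol <- function(x, ...) {
  cat("<fear_protocol> ", x$name, ": ",
      sum(x$epochs$channel == "CS"), " CS / ",
      sum(x$epochs$channel == "US"), " US epochs over ",
      x$duration_s, " s", sep = "")
  if (length(x$session_boundaries))
    cat("; session boundaries at ",
        paste(x$session_boundaries, collapse = ", "), " s", sep = "")
  cat("\n")
  invisible(x)
}

# Per-step channel amplitude vectors for the engine.
epoch_amplitudes <- function(protocol, dt_ms, settle_s = 0) {
  steps <- ceiling((protocol$duration_s + settle_s) * 1000 / dt_ms)
  cs <- numeric(steps); us <- numeric(steps)
  tm <- (seq_len(steps) - 0.5) * dt_ms / 1000 - settle_s  # mid-step time
  for (i in seq_len(nrow(protocol$epochs))) {
    e <- protocol$epochs[i, ]
    on <- tm >= e$t_start & tm < e$t_start + e$duration
    if (e$channel == "CS") cs[on] <- e$amplitude else us[on] <- e$amplitude
  }
  list(cs = cs, us = us, steps = steps,
       time_s = (seq_len(steps)) * dt_ms / 1000 - settle_s)
}
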