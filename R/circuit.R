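#' Construct a fear-circuit model
#'
#' Assembles units, connections, and external inputs into a validated
#' `fear_circuit` object, the central container of the package.  Most users
#' will start from \code{\link{build_default_circuit}} and modify it rather
#' than assembling a circuit from scratch.
#'
#' @param units Data frame with one row per unit and columns `name`, `tau`
#'   (ms), `tonic` (remapped-potential units), `phi` (Hz), `psi`
#'   (remapped-potential units), `polarity` ("excitatory"/"inhibitory"), and
#'   `neuron_class` ("pyramidal", "parvalbumin", "somatostatin", "vip",
#'   "cck", "other").
#' @param connections Data frame with one row per directed connection and
#'   columns `pre` (unit name, or the external channels `"CS"`/`"US"`),
#'   `post` (unit name), `weight` (non-negative efficacy), and optional
#'   plasticity columns `rule` (`NA`, `"LTP"`, `"LTP_LTD"`, `"DSI"`,
#'   `"DSE"`), `eta`, `eta_ltd`, `M`, `sigma`.
#' @param external_inputs Named list giving the drive value of the CS and US
#'   channels while on (default 100 each).
#' @param theta_dsi Depolarization threshold, as a fraction of a unit's
#'   maximum rate, above which its DSI/DSE timer accumulates (default 0.2).
#' @param trigger_s Continuous depolarization time (s) required before
#'   DSI/DSE engages (default 10).
#' @return An object of class `fear_circuit`.
#' @seealso \code{\link{build_default_circuit}}, \code{\link{run_protocol}}
#' @export
fear_circuit <- function(units, connections,
                         external_inputs = list(CS = 100, US = 100),
                         theta_dsi = 0.2, trigger_s = 10) {
  units <- as.data.frame(units, stringsAsFactors = FALSE)
  connections <- as.data.frame(connections, stringsAsFactors = FALSE)
  need_u <- c("name", "tau", "tonic", "phi", "psi", "polarity", "neuron_class")
  miss <- setdiff(need_u, names(units))
  if (length(miss))
    stop("`units` is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (col in c("rule", "eta", "eta_ltd", "M", "sigma")) {
    if (is.null(connections[[col]])) connections[[col]] <- NA
  }
  if (is.null(connections$initial_weight))
    connections$initial_weight <- connections$weight

  if (anyDuplicated(units$name))
    stop("duplicate unit name(s): ",
         paste(unique(units$name[duplicated(units$name)]), collapse = ", "),
         call. = FALSE)
  if (any(units$tau <= 0)) stop("unit `tau` must be positive", call. = FALSE)
  if (any(units$phi <= 0)) stop("unit `phi` must be positive", call. = FALSE)
  if (any(units$psi < 0 | units$psi >= pi))
    stop("unit `psi` must lie in [0, pi)", call. = FALSE)
  if (any(units$tonic < 0)) stop("unit `tonic` must be >= 0", call. = FALSE)
  if (!all(units$polarity %in% c("excitatory", "inhibitory")))
    stop("unit `polarity` must be 'excitatory' or 'inhibitory'", call. = FALSE)

  valid_pre <- c(units$name, "CS", "US")
  bad <- setdiff(connections$pre, valid_pre)
  if (length(bad))
    stop("connection presynaptic endpoint(s) not declared: ",
         paste(bad, collapse = ", "), call. = FALSE)
  bad <- setdiff(connections$post, units$name)
  if (length(bad))
    stop("connection postsynaptic endpoint(s) not declared: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (any(connections$weight < 0))
    stop("connection weights must be non-negative", call. = FALSE)
  if (anyDuplicated(paste(connections$pre, connections$post)))
    stop("duplicate connection(s)", call. = FALSE)
  ok_rule <- is.na(connections$rule) |
    connections$rule %in% c("LTP", "LTP_LTD", "DSI", "DSE")
  if (!all(ok_rule))
    stop("unknown plasticity rule: ",
         paste(unique(connections$rule[!ok_rule]), collapse = ", "),
         call. = FALSE)
  pl <- !is.na(connections$rule)
  if (any(pl & (is.na(connections$eta) | connections$eta < 0)))
    stop("plastic connections need a non-negative `eta`", call. = FALSE)
  hebb <- pl & connections$rule %in% c("LTP", "LTP_LTD")
  if (any(hebb & is.na(connections$M)))
    connections$M[hebb & is.na(connections$M)] <-
      3 * connections$initial_weight[hebb & is.na(connections$M)]
  if (any(hebb & (connections$M <= 0)))
    stop("LTP/LTD ceiling `M` must be positive", call. = FALSE)
  if (any(hebb & (is.na(connections$sigma) | connections$sigma < 0 |
                    connections$sigma > 1)))
    stop("LTP/LTD connections need `sigma` in [0, 1]", call. = FALSE)
  ltd <- pl & connections$rule == "LTP_LTD" & is.na(connections$eta_ltd)
  connections$eta_ltd[ltd] <- connections$eta[ltd]
  if (!all(c("CS", "US") %in% names(external_inputs)))
    stop("`external_inputs` must name both CS and US", call. = FALSE)

  structure(list(units = units, connections = connections,
                 external_inputs = external_inputs,
                 theta_dsi = theta_dsi, trigger_s = trigger_s),
            class = "fear_circuit")
}

#' @export
print.fear_circuit <- function(x, ...) {
  n_exc <- sum(x$units$polarity == "excitatory")
  n_inh <- sum(x$units$polarity == "inhibitory")
  pl <- x$connections[!is.na(x$connections$rule), , drop = FALSE]
  cat("<fear_circuit> ", nrow(x$units), " units (", n_exc, " excitatory, ",
      n_inh, " inhibitory), ", nrow(x$connections), " connections (",
      nrow(pl), " plastic)\n", sep = "")
  cat("  external drive: CS = ", x$external_inputs$CS,
      ", US = ", x$external_inputs$US,
      "; DSI/DSE trigger = ", x$trigger_s, " s at ",
      round(100 * x$theta_dsi), "% of phi\n", sep = "")
  if (nrow(pl)) {
    cat("  plastic:", paste(sprintf("%s->%s [%s]", pl$pre, pl$post, pl$rule),
                            collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.fear_circuit <- function(object, ...) {
  print(object)
  cat("\nUnits:\n")
  print(object$units, row.names = FALSE, digits = 4)
  cat("\nConnections:\n")
  print(object$connections, row.names = FALSE, digits = 4)
  invisible(object)
}

#' Snapshot and restore connection weights
#'
#' `snapshot_weights` returns a named vector of every connection weight
#' (names `"pre->post"`).  `restore_weights` writes such a table back into
#' the circuit; with `only_transient = TRUE` only DSI/DSE-attached
#' connections are restored, which is the between-session reset of the
#' transient endocannabinoid depression (weights changed by LTP/LTD
#' persist).
#'
#' @param model A `fear_circuit`.
#' @param table Named numeric vector as returned by `snapshot_weights`.
#' @param only_transient Restore only DSI/DSE connections? Default `FALSE`.
#' @return `snapshot_weights`: named numeric vector.  `restore_weights`: the
#'   modified `fear_circuit`.
#' @export
snapshot_weights <- function(model) {
  stopifnot(inherits(model, "fear_circuit"))
  stats::setNames(model$connections$weight, connection_ids(model))
}

#' @rdname snapshot_weights
#' @export
restore_weights <- function(model, table, only_transient = FALSE) {
  stopifnot(inherits(model, "fear_circuit"))
  ids <- connection_ids(model)
  if (!all(ids %in% names(table)))
    stop("`table` does not cover all connections", call. = FALSE)
  sel <- if (only_transient)
    !is.na(model$connections$rule) & model$connections$rule %in% c("DSI", "DSE")
  else rep(TRUE, nrow(model$connections))
  model$connections$weight[sel] <- unname(table[ids[sel]])
  model
}

connection_ids <- function(model) {
  paste0(model$connections$pre, "->", model$connections$post)
}

#' Look up a connection weight
#'
#' @param model A `fear_circuit`.
#' @param pre,post Endpoint names (`pre` may be `"CS"` or `"US"`).
#' @return The weight (scalar).
#' @export
connection_weight <- function(model, pre, post) {
  i <- match_connection(model, pre, post)
  model$connections$weight[i]
}

match_connection <- function(model, pre, post) {
  i <- which(model$connections$pre == pre & model$connections$post == post)
  if (length(i) != 1L)
    stop("no connection ", pre, "->", post, call. = FALSE)
  i
}

#' Set a connection weight
#'
#' @inheritParams connection_weight
#' @param value New non-negative weight.
#' @param reset_initial Also reset the connection's `initial_weight` (and
#'   rescale an LTP/LTD ceiling defined as a multiple of it)? Default
#'   `FALSE`: the stored initial weight, used by between-session resets and
#'   the weight ceiling, is kept.
#' @return The modified `fear_circuit`.
#' @export
set_connection_weight <- function(model, pre, post, value,
                                  reset_initial = FALSE) {
  stopifnot(value >= 0)
  i <- match_connection(model, pre, post)
  if (reset_initial) {
    old0 <- model$connections$initial_weight[i]
    if (!is.na(model$connections$M[i]) && old0 > 0) {
      model$connections$M[i] <- model$connections$M[i] / old0 * value
    }
    model$connections$initial_weight[i] <- value
  }
  model$connections$weight[i] <- value
  model
}

# Compile a circuit into the flat arrays consumed by the simulation engine.
compile_circuit <- function(model) {
  u <- model$units
  cn <- model$connections
  n <- nrow(u)
  idx <- stats::setNames(seq_len(n), u$name)
  pre_idx <- ifelse(cn$pre == "CS", n + 1L,
                    ifelse(cn$pre == "US", n + 2L, idx[cn$pre]))
  sign <- ifelse(cn$pre %in% c("CS", "US"), 1,
                 ifelse(u$polarity[pmin(pre_idx, n)] == "inhibitory", -1, 1))
  rule_code <- match(cn$rule, c("LTP", "LTP_LTD", "DSI", "DSE"))
  rule_code[is.na(rule_code)] <- 0L
  list(n = n, names = u$name, idx = idx,
       tau = u$tau, tonic = u$tonic, phi = u$phi, psi = u$psi,
       pre = as.integer(pre_idx), post = as.integer(idx[cn$post]),
       sign = as.numeric(sign), w = cn$weight,
       w_init = cn$initial_weight,
       rule = as.integer(rule_code),
       eta = ifelse(is.na(cn$eta), 0, cn$eta),
       eta_ltd = ifelse(is.na(cn$eta_ltd), 0, cn$eta_ltd),
       M = ifelse(is.na(cn$M), 0, cn$M),
       sigma = ifelse(is.na(cn$sigma), 0, cn$sigma),
       transient = cn$rule %in% c("DSI", "DSE") & !is.na(cn$rule),
       cs_drive = model$external_inputs$CS,
       us_drive = model$external_inputs$US,
       theta_dsi = model$theta_dsi, trigger_s = model$trigger_s,
       conn_id = connection_ids(model))
}
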