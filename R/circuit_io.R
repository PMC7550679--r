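#' Read and write circuit configurations (YAML)
#'
#' `save_circuit` writes a `fear_circuit` to a structured-text YAML file
#' with sections `units`, `connections`, `external_inputs` and `options`
#' (plus a schema `version`); `load_circuit` reads one back through the
#' same validation as \code{\link{fear_circuit}}, so malformed files fail
#' with an informative error.  The round trip is lossless.
#'
#' @param model A \code{\link{fear_circuit}}.
#' @param path File path.
#' @return `load_circuit`: a `fear_circuit`; `save_circuit`: `path`,
#'   invisibly.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' save_circuit(build_default_circuit(), f)
#' circ <- load_circuit(f)
#' @export
save_circuit <- function(model, path) {
  stopifnot(inherits(model, "fear_circuit"))
  un <- lapply(seq_len(nrow(model$units)), function(i)
    as.list(model$units[i, c("name", "tau", "tonic", "phi", "psi",
                             "polarity", "neuron_class")]))
  cn <- lapply(seq_len(nrow(model$connections)), function(i) {
    row <- model$connections[i, ]
    x <- list(pre = row$pre, post = row$post, weight = row$weight)
    if (!is.na(row$rule)) {
      x$plasticity <- list(rule = row$rule, eta = row$eta)
      if (row$rule == "LTP_LTD") x$plasticity$eta_ltd <- row$eta_ltd
      if (row$rule %in% c("LTP", "LTP_LTD")) {
        x$plasticity$M <- row$M
        x$plasticity$sigma <- row$sigma
      }
    }
    x
  })
  obj <- list(version = 1L,
              external_inputs = model$external_inputs,
              options = list(theta_dsi = model$theta_dsi,
                             trigger_s = model$trigger_s),
              units = un, connections = cn)
  yaml::write_yaml(obj, path, precision = 12L)
  invisible(path)
}

#' @rdname save_circuit
#' @export
load_circuit <- function(path) {
  obj <- yaml::read_yaml(path)
  for (need in c("units", "connections", "external_inputs"))
    if (is.null(obj[[need]]))
      stop("circuit config lacks section `", need, "`", call. = FALSE)
  units <- do.call(rbind, lapply(obj$units, function(u) {
    for (need in c("name", "tau", "tonic", "phi", "psi", "polarity",
                   "neuron_class"))
      if (is.null(u[[need]]))
        stop("unit entry missing field `", need, "`", call. = FALSE)
    data.frame(name = u$name, tau = u$tau, tonic = u$tonic, phi = u$phi,
               psi = u$psi, polarity = u$polarity,
               neuron_class = u$neuron_class, stringsAsFactors = FALSE)
  }))
  conns <- do.call(rbind, lapply(obj$connections, function(cn) {
    for (need in c("pre", "post", "weight"))
      if (is.null(cn[[need]]))
        stop("connection entry missing field `", need, "`", call. = FALSE)
    pl <- cn$plasticity
    if (!is.null(pl) && is.null(pl$rule))
      stop("plasticity spec for ", cn$pre, "->", cn$post,
           " missing `rule`", call. = FALSE)
    data.frame(pre = cn$pre, post = cn$post, weight = cn$weight,
               rule = if (is.null(pl)) NA_character_ else pl$rule,
               eta = if (is.null(pl$eta)) NA_real_ else pl$eta,
               eta_ltd = if (is.null(pl$eta_ltd)) NA_real_ else pl$eta_ltd,
               M = if (is.null(pl$M)) NA_real_ else pl$M,
               sigma = if (is.null(pl$sigma)) NA_real_ else pl$sigma,
               stringsAsFactors = FALSE)
  }))
  opts <- obj$options
  fear_circuit(units, conns, external_inputs = obj$external_inputs,
               theta_dsi = if (is.null(opts$theta_dsi)) 0.1 else
                 opts$theta_dsi,
               trigger_s = if (is.null(opts$trigger_s)) 10 else
                 opts$trigger_s)
}

#' Export a trace as tidy long-format text
#'
#' Writes `time_s, series, value` rows (activations in Hz keyed by unit
#' name; weights keyed by `"w:pre->post"`) to a CSV readable by any
#' downstream tool.
#'
#' @param trace A `fear_trace`.
#' @param path Output file.
#' @param weights Include connection-weight series? Default `TRUE`.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, weights = TRUE) {
  stopifnot(inherits(trace, "fear_trace"))
  long <- data.frame(
    time_s = rep(trace$time_s, ncol(trace$A)),
    series = rep(colnames(trace$A), each = nrow(trace$A)),
    value = as.vector(trace$A))
  if (weights) {
    pl <- which(!is.na(trace$model$connections$rule))
    wl <- data.frame(
      time_s = rep(trace$time_s, length(pl)),
      series = rep(paste0("w:", colnames(trace$W)[pl]),
                   each = nrow(trace$W)),
      value = as.vector(trace$W[, pl]))
    long <- rbind(long, wl)
  }
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Read back a trace written by [write_trace()]
#'
#' @param path CSV file produced by `write_trace`.
#' @return Data frame in long format (`time_s`, `series`, `value`).
#' @export
read_trace <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
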