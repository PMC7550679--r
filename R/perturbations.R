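#' In-silico perturbations: lesions, stimulation, weight overrides, blockades
#'
#' Constructs a perturbation to be applied during \code{\link{run_protocol}}.
#' Supported kinds mirror the classic experimental manipulations:
#' \describe{
#'   \item{`lesion_unit`}{output of the unit forced to 0 (TTX/muscimol-style
#'     inactivation).}
#'   \item{`clamp_unit_max`}{output forced to the unit's maximum rate
#'     (optogenetic-style stimulation).}
#'   \item{`clamp_unit_value`}{output forced to `value` Hz.}
#'   \item{`set_connection`}{weight held at `value` for the window (weight
#'     restored afterwards; plasticity suspended on the held connection).}
#'   \item{`zero_region_weights`}{all weights into and out of units whose
#'     name starts with `target` held at 0 (regional TTX).}
#'   \item{`clamp_connection_output`}{the connection's contribution forced to
#'     0 (`value = 0`) or to weight x presynaptic maximum (`value = "max"`),
#'     as in pathway-terminal inactivation/stimulation.}
#'   \item{`block_plasticity`}{weight updates suspended; `target` may be a
#'     rule name (`"DSI"`, `"DSE"`, `"DSI/DSE"`, `"LTP_LTD"`, `"all"`)
#'     optionally restricted with `region` (unit-name prefix of the
#'     postsynaptic unit, e.g. `"BA"`, `"CeM"`), or a single connection id
#'     `"pre->post"`.}
#' }
#'
#' @param kind Perturbation kind (see above).
#' @param target Unit name, `"pre->post"` connection id, region prefix, or
#'   rule name, depending on `kind`.
#' @param window Numeric `c(start_s, end_s)` in protocol time (settle time
#'   excluded); defaults to the whole run.
#' @param value Optional value (see kinds).
#' @param region Optional region prefix for `block_plasticity`.
#' @return A `fear_perturbation` object.
#' @examples
#' pl_ttx <- perturbation("zero_region_weights", "PL", window = c(0, 180))
#' no_dsi <- perturbation("block_plasticity", "DSI/DSE", region = "BA")
#' @export
perturbation <- function(kind, target, window = c(0, Inf), value = NULL,
                         region = NULL) {
  kinds <- c("lesion_unit", "clamp_unit_max", "clamp_unit_value",
             "set_connection", "zero_region_weights",
             "clamp_connection_output", "block_plasticity")
  if (!kind %in% kinds)
    stop("unknown perturbation kind: ", kind, call. = FALSE)
  if (length(window) != 2 || window[2] < window[1])
    stop("`window` must be c(start, end) with end >= start", call. = FALSE)
  structure(list(kind = kind, target = target, window = window,
                 value = value, region = region),
            class = "fear_perturbation")
}

# Compile perturbations into the step-indexed tables the engine consumes.
compile_perturbations <- function(perts, net, model, dt_ms, settle_steps,
                                  total_steps) {
  uc <- data.frame(unit = integer(0), start = integer(0), end = integer(0),
                   mode = integer(0), value = numeric(0))
  co <- data.frame(conn = integer(0), start = integer(0), end = integer(0),
                   mode = integer(0), value = numeric(0))
  pb <- data.frame(conn = integer(0), start = integer(0), end = integer(0))
  if (is.null(perts)) perts <- list()
  if (inherits(perts, "fear_perturbation")) perts <- list(perts)
  ids <- net$conn_id
  win_steps <- function(w) {
    s <- if (is.finite(w[1])) settle_steps + floor(w[1] * 1000 / dt_ms) + 1L
         else 1L
    e <- if (is.finite(w[2])) settle_steps + ceiling(w[2] * 1000 / dt_ms)
         else total_steps
    c(max(1L, s), min(total_steps, e))
  }
  unit_index <- function(nm) {
    i <- match(nm, net$names)
    if (is.na(i)) stop("unknown unit in perturbation: ", nm, call. = FALSE)
    i
  }
  conn_index <- function(id) {
    i <- match(id, ids)
    if (is.na(i)) stop("unknown connection in perturbation: ", id,
                       call. = FALSE)
    i
  }
  for (p in perts) {
    stopifnot(inherits(p, "fear_perturbation"))
    w <- win_steps(p$window)
    if (p$kind == "lesion_unit") {
      for (nm in p$target)
        uc <- rbind(uc, data.frame(unit = unit_index(nm), start = w[1],
                                   end = w[2], mode = 0L, value = 0))
    } else if (p$kind == "clamp_unit_max") {
      for (nm in p$target)
        uc <- rbind(uc, data.frame(unit = unit_index(nm), start = w[1],
                                   end = w[2], mode = 1L, value = 0))
    } else if (p$kind == "clamp_unit_value") {
      uc <- rbind(uc, data.frame(unit = unit_index(p$target), start = w[1],
                                 end = w[2], mode = 2L,
                                 value = as.numeric(p$value)))
    } else if (p$kind == "set_connection") {
      co <- rbind(co, data.frame(conn = conn_index(p$target), start = w[1],
                                 end = w[2], mode = 0L,
                                 value = as.numeric(p$value)))
    } else if (p$kind == "zero_region_weights") {
      in_region <- startsWith(net$names, p$target)
      if (!any(in_region))
        stop("no units match region: ", p$target, call. = FALSE)
      touch <- (net$pre <= net$n & in_region[pmin(net$pre, net$n)]) |
        in_region[net$post]
      for (ci in which(touch))
        co <- rbind(co, data.frame(conn = ci, start = w[1], end = w[2],
                                   mode = 0L, value = 0))
    } else if (p$kind == "clamp_connection_output") {
      md <- if (identical(p$value, "max")) 2L else 1L
      co <- rbind(co, data.frame(conn = conn_index(p$target), start = w[1],
                                 end = w[2], mode = md, value = 0))
    } else if (p$kind == "block_plasticity") {
      sel <- if (grepl("->", p$target, fixed = TRUE)) {
        seq_along(ids) == conn_index(p$target)
      } else if (p$target == "all") {
        net$rule > 0
      } else if (p$target %in% c("DSI/DSE", "DSI_DSE")) {
        net$rule %in% c(3L, 4L)
      } else if (p$target == "DSI") {
        net$rule == 3L
      } else if (p$target == "DSE") {
        net$rule == 4L
      } else if (p$target %in% c("LTP", "LTP_LTD")) {
        net$rule %in% c(1L, 2L)
      } else stop("unknown blockade target: ", p$target, call. = FALSE)
      if (!is.null(p$region)) {
        if (!any(startsWith(net$names, p$region)))
          stop("unknown blockade region: ", p$region, call. = FALSE)
        sel <- sel & startsWith(net$names[net$post], p$region)
      }
      for (ci in which(sel))
        pb <- rbind(pb, data.frame(conn = ci, start = w[1], end = w[2]))
    }
  }
  list(uc = uc, co = co, pb = pb)
}
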