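#' Parameters scanned by the one-factor-at-a-time analysis
#'
#' All connection weights plus all plasticity constants (learning and
#' depression rates) of a circuit, as parameter ids understood by
#' \code{\link{oat_scan}}: `"w:pre->post"`, `"eta:pre->post"` and
#' `"eta_ltd:pre->post"`.
#'
#' @param model A \code{\link{fear_circuit}}.
#' @return Character vector of parameter ids.
#' @export
oat_parameters <- function(model) {
  cn <- model$connections
  ids <- paste0(cn$pre, "->", cn$post)
  out <- paste0("w:", ids)
  pl <- !is.na(cn$rule)
  out <- c(out, paste0("eta:", ids[pl]))
  ltd <- pl & cn$rule == "LTP_LTD"
  c(out, paste0("eta_ltd:", ids[ltd]))
}

oat_get <- function(model, id) {
  p <- strsplit(id, ":", fixed = TRUE)[[1]]
  ep <- strsplit(p[2], "->", fixed = TRUE)[[1]]
  i <- which(model$connections$pre == ep[1] &
               model$connections$post == ep[2])
  col <- c(w = "weight", eta = "eta", eta_ltd = "eta_ltd")[p[1]]
  model$connections[i, col]
}

oat_set <- function(model, id, value) {
  p <- strsplit(id, ":", fixed = TRUE)[[1]]
  ep <- strsplit(p[2], "->", fixed = TRUE)[[1]]
  i <- which(model$connections$pre == ep[1] &
               model$connections$post == ep[2])
  col <- c(w = "weight", eta = "eta", eta_ltd = "eta_ltd")[p[1]]
  model$connections[i, col] <- value
  if (col == "weight") {
    # a scanned weight is a new reference configuration
    old0 <- model$connections$initial_weight[i]
    if (!is.na(model$connections$M[i]) && old0 > 0)
      model$connections$M[i] <- model$connections$M[i] / old0 * value
    model$connections$initial_weight[i] <- value
  }
  fear_circuit(model$units, model$connections, model$external_inputs,
               model$theta_dsi, model$trigger_s)
}

#' One-factor-at-a-time sensitivity scan
#'
#' For each parameter (connection weights and plasticity constants), moves
#' its value away from the reference in steps of `step_frac` (5% by
#' default), one direction at a time with every other parameter fixed, and
#' records the first value at which at least one registered experiment is
#' lost.  The scan stops at -100% (parameter removable) and at
#' `+100 * cap_frac`% (robust to large increase).
#'
#' The reference configuration must pass all scanned experiments, otherwise
#' the notion of "first experiment lost" is meaningless.
#'
#' @param model A \code{\link{fear_circuit}}.
#' @param params Parameter ids (default: all from
#'   \code{\link{oat_parameters}}).
#' @param step_frac Scan step as a fraction of the reference value.
#' @param cap_frac Upper scan bound as a multiple of the reference (10 =
#'   +1000%).
#' @param ids Registry experiment ids to score against (default: all
#'   experiments that pass on the reference; a `fast` subset keeps the
#'   scan affordable).
#' @param fast Use coarse 25% steps and the core behavioral subset
#'   (conditioning, extinction course, taxonomy, reinstatement).
#' @param cfg A \code{\link{sim_config}}.
#' @param criteria A \code{\link{criteria_config}}.
#' @param verbose Print progress.
#' @return A `fear_oat_report` data frame: parameter, reference value,
#'   lower/upper failure boundaries (% change; `-100` = removable,
#'   `Inf` = above the cap), and the first experiment lost at each
#'   boundary.
#' @export
oat_scan <- function(model, params = NULL, step_frac = 0.05, cap_frac = 10,
                     ids = NULL, fast = FALSE, cfg = sim_config(record_every = 5),
                     criteria = criteria_config(), verbose = interactive()) {
  if (fast) {
    step_frac <- max(step_frac, 0.25)
    if (is.null(ids))
      ids <- c("cond_acquisition", "within_session_extinction",
               "between_session_extinction", "reinstatement",
               "unit_taxonomy")
  }
  if (is.null(params)) params <- oat_parameters(model)
  ref <- run_registry(model, cfg, criteria, ids = ids)
  if (!all(ref$pass)) {
    if (is.null(ids)) {
      ids <- ref$id[ref$pass]
      ref <- ref[ref$pass, ]
    } else {
      stop("reference configuration fails: ",
           paste(ref$id[!ref$pass], collapse = ", "), call. = FALSE)
    }
  }
  lost_first <- function(m) {
    r <- try(run_registry(m, cfg, criteria, ids = ids), silent = TRUE)
    if (inherits(r, "try-error")) return("simulation-error")
    bad <- r$id[!r$pass]
    if (length(bad)) bad[1] else NA_character_
  }
  rows <- lapply(params, function(pid) {
    v0 <- oat_get(model, pid)
    scan_dir <- function(dir) {
      k <- 1
      repeat {
        f <- 1 + dir * step_frac * k
        if (dir < 0 && f < -1e-9) return(list(bound = -100, lost = NA))
        if (dir > 0 && f > cap_frac + 1e-9)
          return(list(bound = Inf, lost = NA))
        f <- max(f, 0)
        lost <- lost_first(oat_set(model, pid, v0 * f))
        if (!is.na(lost))
          return(list(bound = 100 * (f - 1), lost = lost))
        if (f == 0) return(list(bound = -100, lost = NA))
        k <- k + 1
      }
    }
    lo <- scan_dir(-1); hi <- scan_dir(+1)
    if (verbose)
      cat(sprintf("%-22s [%6.0f%%, %6.0f%%] %s | %s\n", pid, lo$bound,
                  hi$bound, ifelse(is.na(lo$lost), "", lo$lost),
                  ifelse(is.na(hi$lost), "", hi$lost)))
    data.frame(parameter = pid, reference = v0,
               lower_pct = lo$bound, upper_pct = hi$bound,
               lost_lower = ifelse(is.na(lo$lost), "", lo$lost),
               lost_upper = ifelse(is.na(hi$lost), "", hi$lost))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, step_frac = step_frac, cap_frac = cap_frac,
            experiments = ids, class = c("fear_oat_report", "data.frame"))
}

#' @export
print.fear_oat_report <- function(x, ...) {
  cat(sprintf("<fear_oat_report> %d parameters, step %.0f%%, cap +%.0f%%\n",
              nrow(x), 100 * attr(x, "step_frac"),
              100 * attr(x, "cap_frac")))
  print(as.data.frame(x), row.names = FALSE, right = FALSE, digits = 4)
  invisible(x)
}

#' Parameters removable without losing any experiment
#'
#' Lists the scanned parameters whose lower failure boundary reached -100%:
#' their value can be set to zero without losing any registered target
#' experiment (the criterion used to prune the legacy connections).
#'
#' @param report A `fear_oat_report` from \code{\link{oat_scan}}.
#' @return Character vector of parameter ids (possibly empty).
#' @export
prune_removable <- function(report) {
  stopifnot(inherits(report, "fear_oat_report"))
  as.character(report$parameter[report$lower_pct <= -100])
}
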