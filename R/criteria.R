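#' Operational pass criteria
#'
#' The three activity/plasticity thresholds used to score every experiment:
#' a unit counts as *active* at 20% of its maximum rate; CeM expresses fear
#' at 70% of its maximum; LTP/LTD counts as detected at a 20% change of the
#' evoked PSP.
#'
#' @param unit_active_frac Fraction of phi above which a unit is active.
#' @param cem_fear_frac Fraction of CeM's phi above which fear is expressed.
#' @param psp_change_frac Fractional PSP change that counts as plasticity.
#' @return A `criteria_config` list.
#' @export
criteria_config <- function(unit_active_frac = 0.20, cem_fear_frac = 0.70,
                            psp_change_frac = 0.20) {
  stopifnot(unit_active_frac > 0, unit_active_frac < 1,
            cem_fear_frac > 0, cem_fear_frac < 1,
            psp_change_frac > 0, psp_change_frac < 1)
  structure(list(unit_active_frac = unit_active_frac,
                 cem_fear_frac = cem_fear_frac,
                 psp_change_frac = psp_change_frac),
            class = "criteria_config")
}
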