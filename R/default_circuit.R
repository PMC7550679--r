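#' Build the calibrated default fear circuit
#'
#' Returns the 21-unit amygdala-prefrontal circuit with its calibrated
#' default parameters: 9 excitatory (pyramidal) units -- LAp1, LAp2,
#' BAp1..BAp5, PLp, ILp -- and 12 inhibitory units -- LApv, LAvip, BAcck,
#' BApv, CeLon, CeLoff, CeM, ITC, PLpv, PLs, ILpv, ILs.  The CS and US
#' enter as external step inputs of drive 100.  Eight connections are
#' plastic: CS->LAp1 (LTP), LAp2->CeLon (LTP), PLp->BAp4 (LTP/LTD),
#' BAp2->ILp (LTP/LTD), BAp3->ITC (LTP), BAcck->BAp2 (DSI), BAp4->CeM and
#' BAp5->CeM (DSE).  LTP/LTD ceilings are 3x the initial weight and the
#' DSI/DSE trigger is 10 s of sustained postsynaptic depolarization.
#'
#' Electrophysiological constants follow the population literature in
#' relative terms: time constants lie in 7.7--35.6 ms, tonic drives are
#' proportional to basal rates of 0.3 Hz (pyramidal), 1.3 Hz (most
#' interneurons and output units) and 5.3 Hz (parvalbumin-like units,
#' including the CCK basket cells, which share fast-spiking kinetics).
#' Connection weights not printed in the source literature were calibrated
#' against the experiment registry (see the package vignette); the anchored
#' values are LAp1->BAp1 = 7.0, LAp1->BAp2 = 5.0, LAp1->BAp5 = 3.0 and
#' BAcck->BAp1 = BAcck->BAp2 = 0.7.
#'
#' @param legacy_connections Re-enable the three connections pruned by the
#'   sensitivity analysis (a BApv2 unit with ILp->BApv2 and BApv2->BAp3,
#'   plus a direct US->CeM input), at zero-effect weights, for exploration.
#' @return A validated \code{\link{fear_circuit}}.
#' @examples
#' circ <- build_default_circuit()
#' print(circ)
#' @export
build_default_circuit <- function(legacy_connections = FALSE) {
  # tonic drive = tonic_scale * basal rate (0.3 / 1.3 / 5.3 Hz)
  ts <- 0.25
  t_pyr <- ts * 0.3; t_int <- ts * 1.3; t_pv <- ts * 5.3

  U <- function(name, tau, tonic, phi, psi, polarity, neuron_class) {
    data.frame(name = name, tau = tau, tonic = tonic, phi = phi, psi = psi,
               polarity = polarity, neuron_class = neuron_class,
               stringsAsFactors = FALSE)
  }
  units <- rbind(
    U("LAp1",   10, t_pyr, 16, 1.886, "excitatory", "pyramidal"),
    U("LAp2",   25, t_pyr, 20, 0.80, "excitatory", "pyramidal"),
    U("LApv",   12, t_pv,  80, 0.30, "inhibitory", "parvalbumin"),
    U("LAvip",  12, t_int, 60, 0.50, "inhibitory", "vip"),
    U("BAp1",   25, t_pyr, 20, 0.70, "excitatory", "pyramidal"),
    U("BAp2",   10, t_pyr, 20, 0.30, "excitatory", "pyramidal"),
    U("BAp3",   25, t_pyr, 20, 0.50, "excitatory", "pyramidal"),
    U("BAp4",   25, t_pyr, 20, 0.70, "excitatory", "pyramidal"),
    U("BAp5",   25, t_pyr, 20, 0.70, "excitatory", "pyramidal"),
    U("BAcck",  10, t_pv, 110, 1.666, "inhibitory", "cck"),
    U("BApv",   12, t_pv,  80, 1.00, "inhibitory", "parvalbumin"),
    U("CeLon",  15, t_int, 40, 1.20, "inhibitory", "other"),
    U("CeLoff", 15, t_int, 40, 0.00, "inhibitory", "other"),
    U("CeM",    18, t_int, 40, 0.30, "inhibitory", "other"),
    U("ITC",    15, t_int, 30, 1.52, "inhibitory", "other"),
    U("PLp",    25, t_pyr, 30, 0.30, "excitatory", "pyramidal"),
    U("PLpv",   12, t_pv,  80, 0.30, "inhibitory", "parvalbumin"),
    U("PLs",    15, t_int, 30, 0.60, "inhibitory", "somatostatin"),
    U("ILp",    10, t_pyr, 20, 0.10, "excitatory", "pyramidal"),
    U("ILpv", 35.6, t_pv,  80, 0.30, "inhibitory", "parvalbumin"),
    U("ILs",    15, t_int, 30, 0.10, "inhibitory", "somatostatin")
  )

  C <- function(pre, post, weight, rule = NA, eta = NA, eta_ltd = NA,
                M = NA, sigma = NA) {
    data.frame(pre = pre, post = post, weight = weight, rule = rule,
               eta = eta, eta_ltd = eta_ltd, M = M, sigma = sigma,
               stringsAsFactors = FALSE)
  }
  conns <- rbind(
    # -- LA input stage --------------------------------------------------
    C("CS", "LAp1", 0.00795, "LTP", eta = 3.0e-4, sigma = 0.50),
    C("CS", "LAp2", 0.0250),
    C("US", "LAp1", 0.02135),
    C("US", "LAvip", 0.0300),
    C("LAvip", "LApv", 0.0400),
    C("LApv", "LAp1", 0.0040),
    C("LApv", "LAp2", 0.0180),
    # -- LA -> BA (anchored fan-out) ------------------------------------
    C("LAp1", "BAp1", 7.0),
    C("LAp1", "BAp2", 5.0),
    C("LAp1", "BAp5", 3.0),
    C("LAp1", "BAcck", 0.1336),
    C("BAcck", "BAp1", 0.7),
    C("BAcck", "BAp2", 0.7, "DSI", eta = 4.2e-8),
    # -- CeL gate --------------------------------------------------------
    C("LAp2", "CeLon", 0.0600, "LTP", eta = 1.0e-4, sigma = 0.05),
    C("CeLon", "CeLoff", 0.0500),
    C("CeLoff", "CeM", 0.1900),
    # -- BA <-> PL fear loop --------------------------------------------
    C("BAp1", "PLp", 0.0400),
    C("BAp1", "PLs", 0.1000),
    C("PLs", "PLpv", 0.1000),
    C("PLpv", "PLp", 0.0300),
    C("PLp", "BApv", 0.0200),
    C("BApv", "BAp4", 0.0100),
    C("PLp", "BAp4", 0.1000, "LTP_LTD", eta = 1.0e-5, eta_ltd = 6.0e-6,
      sigma = 0.20),
    # -- BA <-> IL extinction loop ---------------------------------------
    C("PLp", "ILp", 0.0044),
    C("BAp2", "ILp", 0.1500, "LTP_LTD", eta = 3.8e-8, eta_ltd = 2.2e-3,
      sigma = 0.05),
    C("ILs", "ILpv", 0.1360),
    C("ILpv", "ILp", 0.0545),
    C("US", "ILpv", 0.0070),
    C("ILp", "BAp3", 0.1000),
    C("ILp", "ITC", 0.1500),
    C("BAp3", "ITC", 0.0400, "LTP", eta = 5.4e-7, sigma = 0.10),
    C("ITC", "BAp4", 0.1800),
    # -- output stage ----------------------------------------------------
    C("BAp4", "CeM", 0.0924, "DSE", eta = 9.9e-6),
    C("BAp5", "CeM", 0.0540, "DSE", eta = 7.6e-6)
  )
  if (legacy_connections) {
    units <- rbind(units,
                   U("BApv2", 12, t_pv, 80, 1.00, "inhibitory", "parvalbumin"))
    conns <- rbind(conns,
                   C("ILp", "BApv2", 0),
                   C("BApv2", "BAp3", 0),
                   C("US", "CeM", 0))
  }
  units$basal_hz <- c(pyramidal = 0.3, parvalbumin = 5.3, cck = 5.3,
                      somatostatin = 1.3, vip = 1.3,
                      other = 1.3)[units$neuron_class]
  fear_circuit(units, conns, external_inputs = list(CS = 100, US = 100),
               theta_dsi = 0.1, trigger_s = 10)
}
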