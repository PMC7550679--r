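Package: fearsim
Title: Firing-Rate Simulation of the Amygdala-Prefrontal Fear Circuit
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Deterministic firing-rate (leaky-unit) simulation of the
    amygdala-medial prefrontal cortex circuit underlying cued fear
    conditioning, within- and between-session extinction, and
    reinstatement.  The circuit couples the lateral and basal amygdala,
    the central amygdala gating system (CeL-ON/CeL-OFF/CeM), the
    intercalated cells, and the prelimbic/infralimbic cortices through
    three plasticity rules: a thresholded Hebbian LTP/LTD rule and a
    transient endocannabinoid-style DSI/DSE depression triggered by
    sustained postsynaptic depolarization.  Ships a calibrated default
    circuit, stimulus-protocol builders, in-silico lesion and optogenetic
    perturbations, a registry of 25 target experiments with operational
    pass criteria, PSP probes, and a one-factor-at-a-time sensitivity
    scan.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
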