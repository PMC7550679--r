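# fearsim

Deterministic firing-rate simulation of the amygdala–medial-prefrontal
circuit underlying cued fear conditioning, within- and between-session
extinction, and reinstatement — for computational and systems
neuroscientists who want a compact, fully inspectable circuit-level
account of these learning phenomena and a platform for in-silico lesion,
optogenetic and pharmacological manipulations.

## The model

Twenty-one leaky units (9 excitatory, 12 inhibitory), each a neuronal
population obeying

    tau dU/dt = -U + T + I,    I = sum_i s_i w_i A_i,
    A = phi [tanh(U - psi)]+

with the membrane potential U remapped linearly from (−70, +30) mV onto
(0, π).  The conditioned stimulus (CS, a 20-s tone) and the unconditioned
stimulus (US, a 0.5-s shock) are external step inputs.  Freezing is read
out as activation of the CeM output unit.  Eight connections are plastic
under three rules applied every Euler step (dt = 10 ms):

* Hebbian LTP/LTD: `dW = eta (M − W)(Post − phi·sigma) Pre`, ceiling
  `M = 3 W0`;
* endocannabinoid DSI/DSE: `dW = −eta W Pre`, engaged after 10 s of
  sustained postsynaptic depolarization and *reset between sessions*
  (the transience of the endocannabinoid depression).

Conditioning potentiates the CS pathway and teaches the CeL gate to
release its tonic brake on CeM; within-session extinction is carried by
DSE at the BA→CeM synapses; between-session extinction by DSI-triggered
recruitment of the infralimbic cortex and the intercalated cells; a
single unpaired US reinstates fear.  A registry of 25 in-silico
experiments (lesions, optogenetic toggling, TTX inactivation,
endocannabinoid blockades, IL/PL manipulations) scores the circuit
against the corresponding experimental findings with operational
criteria: a unit is active at 20 % of its maximum rate, fear is expressed
at 70 % of CeM's maximum, plasticity counts at a 20 % PSP change.

## Worked example

```r
library(fearsim)

circ <- build_default_circuit()
print(circ)
#> <fear_circuit> 21 units (9 excitatory, 12 inhibitory), 34 connections (8 plastic)
#>   external drive: CS = 100, US = 100; DSI/DSE trigger = 10 s at 10% of phi

base <- baseline_assessment(circ)
print(base)
#> <fear_baseline> CeM (% of max) per CS:
#>  conditioning: 96 99 98
#>  extinction 1: 99 98 96 92 51 46 40 36 31 27 24 21 19 17 15 13 12 10 10 10
#>  extinction 2: 77 70 64 57 51 46 40 36 31 27 24 21 19 17 15 13 12 10 10 10
#>  reinstatement: 77 74
#>  fear units: BAp4, CeM
#>  extinction units: BAp3, ITC, ILp
#>  persistent units: LAp1, LAp2, LApv, BAp1, BAp2, BAp5, BAcck, BApv, CeLon, PLp, PLs, ILs
```

Reading the course: conditioning drives CeM to its fear ceiling (the
first trial's peak occurs at the US itself — acquisition is fast at
these learning rates); extinction session 1 starts at full fear and
decays as DSE weakens the BA→CeM drive, with the intercalated cells
silencing the fear route mid-session; session 2 starts from a partial
residual (the transient endocannabinoid weights have been forgotten
overnight, the persistent extinction circuit keeps BAp4 suppressed) and
re-extinguishes; after the unpaired US the CS again evokes
above-criterion fear.  The probe taxonomy recovers the fear /
extinction / persistent unit classes.

```r
res <- run_registry(circ)
print(res)
#> <fear_registry_results> 24/25 experiments pass
summary(res)   # per-experiment measured values

rep <- oat_scan(circ, fast = TRUE)   # one-factor-at-a-time robustness
prune_removable(rep)
```

(The one reported failure, reinstatement re-potentiation of PLp→BAp4, is
a structural property of the Hebbian ceiling factor in this architecture;
the methods vignette discusses it.)

A thin command-line front end wraps the same functions:

```sh
Rscript scripts/fearsim.R simulate --protocol full --out out/
Rscript scripts/fearsim.R experiments --out out/
Rscript scripts/fearsim.R sensitivity --fast --out out/
Rscript scripts/calibrate.R --polish        # re-derive the default config
```

## Package layout

* `R/` — circuit container and calibrated default, protocol builders,
  simulation wrapper, perturbations, probes, experiment registry, OAT
  sensitivity scan, YAML/CSV/JSON i/o, plotting.
* `src/engine.cpp` — the Euler/plasticity inner loop.
* `vignettes/fear-circuit-model.Rmd` — the methods vignette: model,
  assumptions, calibration rationale, criteria, limitations.
* `scripts/` — CLI front end, calibration tool, acceptance script.
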