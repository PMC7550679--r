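---
title: "A firing-rate model of the amygdala-prefrontal fear circuit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A firing-rate model of the amygdala-prefrontal fear circuit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fearsim)
```

## The model

`fearsim` simulates cued fear conditioning, extinction and reinstatement
with a deterministic firing-rate network of *leaky units*.  Each unit
stands for a neuronal population and obeys

$$\tau \dot U = -U + T + I, \qquad
  I = \sum_i s_i\, w_i A_i, \qquad
  A = \phi\,[\tanh(U - \psi)]^+ ,$$

where $U$ is the membrane potential remapped linearly from the biological
range $(-70, +30)$ mV onto $(0, \pi)$ (so that the leak pulls toward 0
rather than a negative resting value), $T$ a tonic drive, $I$ the summed
synaptic input, $\psi$ the firing threshold, $\phi$ the maximum rate and
$[x]^+$ rectification.  Weights $w_i \ge 0$ enter with the sign $s_i$ of
the presynaptic population.  Integration is explicit Euler at
$\mathrm{d}t = 10$ ms; because leaky units are low-pass filters the
coarse step is stable, and `sim_config(dt_ms = 1)` reproduces the same
steady states and the same experiment verdicts (the suite checks this).

The circuit has 21 units: 9 excitatory pyramidal populations (LAp1, LAp2,
BAp1–BAp5, PLp, ILp) and 12 inhibitory ones (LApv, LAvip, BAcck, BApv,
CeL-ON, CeL-OFF, CeM, ITC, PLpv, PLs, ILpv, ILs).  CeM — the output unit
whose activation stands for freezing — is counted among the inhibitory
populations, as central-amygdala projection neurons are GABAergic; this is
the only self-consistent reading of the 9/12 split once the IL
interneurons are enumerated.  The CS and US are external step inputs of
drive 100.  Three pathways link input to output: a *persistent* route
(LA→BA→CeM directly through BAp5, and LA→CeL), a *fear* route
(LA→BA→PL→BAp4→CeM), and an *extinction* route (BA→IL→BA/ITC) whose
activation silences the fear route.  CeL-OFF tonically brakes CeM;
conditioning teaches CeL-ON to lift that brake.

Two wiring choices deserve note.  BAcck (the CCK basket population) is
driven feedforward by LAp1, and BApv by PLp: both interneurons are
*persistent*-class units in the probe taxonomy and therefore need a
CS-locked driver; the source text names their targets but not their
afferents.  Likewise the US reaches ILpv directly, implementing the
hypothesis that the aversive stimulus transiently silences infralimbic
pyramidal cells.

## Plasticity

Eight connections are plastic (see `build_default_circuit()`):

* **Hebbian LTP/LTD** — $\Delta W = \eta (M - W)(\mathrm{Post} -
  \phi\sigma)\mathrm{Pre}$, applied every step, clamped to $[0, M]$ with
  $M = 3 W_0$.  Connections reported to show potentiation only
  (CS→LAp1, LAp2→CeL-ON, BAp3→ITC) discard negative deltas; PLp→BAp4 and
  BAp2→ILp use the full rule with separate potentiation and depression
  rates, mirroring their separately reported LTP and LTD.
* **DSI/DSE** — $\Delta W = -\eta W \mathrm{Pre}$, engaged only after the
  postsynaptic unit has been continuously depolarized (≥ `theta_dsi`
  of $\phi$) for 10 s, the endocannabinoid release time.  These changes
  are *transient*: at every session boundary they are returned to their
  pre-protocol values, the model's account of between-session forgetting
  of the endocannabinoid depression.  Boundaries sit between the two
  extinction sessions and before reinstatement; probes of a session's
  outcome ("test day") likewise reset transients first.

Plasticity deltas are scaled by $\mathrm{d}t/10\,\mathrm{ms}$, so weight
trajectories are step-size-independent; the rates $\eta$ are defined per
reference step.  The presynaptic rate entering a delta is the
previous-step activation — the signal the postsynaptic unit actually
integrated that step — which keeps one-step synaptic-lag transients at
stimulus onsets from being paired with a postsynaptic state they never
drove.

`theta_dsi` defaults to 0.1 of $\phi$.  With the tempting alternative of
0.2 (the unit-active criterion) the DSE decay of the BA→CeM weights stalls
exactly at 20 % of CeM's maximum — the classification boundary — leaving
the post-extinction CeM probe undecidable; 0.1 parks the floor at half the
criterion.

## Default configuration and calibration

The source literature prints only a handful of parameter values; they are
honored exactly: LAp1→BAp1 = 7.0, LAp1→BAp2 = 5.0, LAp1→BAp5 = 3.0,
BAcck→BAp1 = BAcck→BAp2 = 0.7, input drive 100, $M = 3W_0$, 10-s DSI/DSE
trigger, dt = 10 ms, $\tau \in [7.7, 35.6]$ ms, and tonic drives
proportional to basal rates of 0.3 / 1.3 / 5.3 Hz (pyramidal / most
interneurons / parvalbumin-like, with BAcck given fast-spiking
parameters).  Every other weight, threshold and rate was calibrated by a
deterministic coordinate-descent search (`scripts/calibrate.R` reproduces
the procedure) against the experiment registry, mirroring the incremental
manual search the model was originally built with.

Several calibrated values are *structurally* tight, and deliberately so:

* **The BAp2 balance.**  With the printed 5.0 excitation and 0.7
  feedforward inhibition, BAp2's drive is a near-cancellation of two
  large terms.  This makes BAp2 a sensitive switch: the slow DSI decay of
  BAcck→BAp2 during extinction tips it from a low rate to saturation,
  which is precisely the mechanism that recruits the infralimbic cortex.
  It also makes BAp2 respond non-monotonically to LAp1's rate: at the
  conditioned CS level (~5 Hz) BAp2 fires; when the paired US saturates
  LAp1, BAcck wins and BAp2 falls silent.  An *unpaired* US, driving LAp1
  only part-way, lands back in the responsive window — this is how a
  reinstatement US can depress BAp2→ILp (presynaptic activity paired with
  US-silenced ILp) while the conditioning USs, which saturate LAp1,
  cannot.
* **ILp's operating point.**  The post-conditioning probe must leave ILp
  *inactive* (< 20 % of $\phi$) while extinction must activate it, and the
  Hebbian threshold of BAp2→ILp must sit below ILp's in-trial rate so
  that transient dips, not steady states, drive depression.  These
  constraints bound the steady PLp→ILp contribution to less than ~0.15
  potential units, which is why that weight is small.

The vignette's quantitative claims about the default configuration are
exactly those computed by the test suite and `scripts/acceptance.R`; the
calibration was chosen once and is not adjusted per analysis.

## Protocols, probes, criteria

The standard in-silico study is four sessions: conditioning (3 CS of
20 s, each ending with a 0.5-s US), two extinction sessions (20
unreinforced CS each) and reinstatement (CS, unpaired US, CS).  Intervals
the source does not state are config defaults documented here: 40-s
inter-trial intervals (every time constant is tens of ms, so activity is
fully at baseline between trials), a 60-s inter-session gap, and a settle
period of five times the largest $\tau$ before the first stimulus so that
the network starts from its tonic fixed point.

Outcomes are scored with three thresholds: a unit is *active* at 20 % of
its maximum rate; CeM expresses *fear* at 70 % of its maximum; plasticity
*counts* at a 20 % change of the evoked PSP.  Session outcomes are read
out with a plasticity-frozen probe CS, measured as the peak sustained
response (the first 2 s after stimulus onset are excluded, so one-step
synaptic-lag transients are not scored).  PSPs are measured slice-style:
the probed connection is isolated, a 30-ms presynaptic stimulation is
calibrated by bisection to evoke just under 10 mV in the reference state,
and the identical drive is replayed against later weight states, making
the percentage change a pure weight readout.  The DSI weakening of
BAcck→BAp2 is scored on the weight itself (> 1 % end-of-session drop)
rather than the 20 % PSP criterion: the near-cancellation described above
amplifies a deliberately small weight change into BAp2's full operating
range, so the calibrated DSI rate is small by design.

## The experiment registry

`run_registry()` evaluates 25 experiments, each keyed to the figure panel
whose finding it reproduces — the four-session behavioral course and unit
taxonomy; the conditioning-, extinction- and reinstatement-induced
plasticity patterns; PL inactivation during conditioning; optogenetic
potentiation/depotentiation toggling of the CS pathway; LA and CeL
inactivation; the CeL-ON/CeL-OFF response reversal; US-substitution by LA
depolarization with its BAp2-block rescue; global, CeM- and BA-restricted
endocannabinoid blockade; and the IL lesion/stimulation and PL→IL pathway
manipulations.  Comparative findings are scored against the shared
control run with explicit margins (typically 5–10 points of CeM's
maximum, or one extinction trial for speed effects); the global
thresholds cover everything else.  Two operationalizations differ from a
literal reading of the texts and are deliberate:

* US-substitution is compared on CeM during the *third training trial*
  (what the corresponding panels actually display).  At this calibration
  the acute recruitment of the extinction circuit — the stated mechanism
  of the weaker conditioning — expresses during training, while the
  persistent traces equalize by the test probe.
* Extinction "speed" under IL stimulation uses the first trial below the
  70 % criterion; the PL→IL silencing effect is scored on early-session
  mean CeM, since at this calibration the crossing index is dominated by
  DSE kinetics.

One registered experiment fails on the shipped configuration and is
reported as such: the reinstatement *re-potentiation of PLp→BAp4*.  The
Hebbian rule's $(M - W)$ ceiling factor makes the threshold rule bistable,
and BAp4 receives excitation only through its plastic prelimbic input; at
every parameterization we explored, either extinction's depotentiation
stalls at the ceiling, or it completes and BAp4 can no longer cross the
Hebbian threshold at the reinstatement US to bootstrap re-potentiation.
A knife-edge depression rate lands in between but does not survive the
dt = 1 ms cross-check, so the robust branch was kept.  The companion
depotentiation of BAp2→ILp at reinstatement, and reinstated fear
behavior itself (carried by the BAp5 route), are reproduced.

## Sensitivity analysis

`oat_scan()` applies the one-factor-at-a-time procedure: each weight and
plasticity constant is moved in 5 % steps away from its reference, other
parameters fixed, until at least one registered experiment is lost; the
report lists both boundaries and the first casualty, and
`prune_removable()` lists parameters whose lower boundary reaches −100 %.
The full scan over all ~45 parameters re-runs the registry hundreds of
times and is a long-running command; `fast = TRUE` (25 % steps, core
behavioral subset) is the CI-scale variant.  Because several calibrated
values sit on structural balance points (see above), a substantial
fraction of parameters tolerate less than ±5 % — a property the original
sensitivity analysis of this circuit also reported.

## What the simulations do and do not show

All inputs are idealized step stimuli and all units are deterministic
rate populations: passing the registry shows that the circuit hypotheses
are *sufficient* to generate the qualitative phenomenology, not that the
parameter values are biologically measured quantities.  Spiking dynamics,
noise, neuromodulators, context/hippocampal effects, renewal, spontaneous
recovery and reconsolidation are out of scope.  Problem sizes used by the
test suite and acceptance script are the study's own: the full
four-session protocol (about 47 simulated minutes, 280k Euler steps)
runs in well under a second through the compiled core, and the registry
in a few seconds.
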