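version: 1
external_inputs:
  CS: 100.0
  US: 100.0
options:
  theta_dsi: 0.1
  trigger_s: 10.0
units:
- name: LAp1
  tau: 10.0
  tonic: 0.075
  phi: 16.0
  psi: 1.886
  polarity: excitatory
  neuron_class: pyramidal
- name: LAp2
  tau: 25.0
  tonic: 0.075
  phi: 20.0
  psi: 0.8
  polarity: excitatory
  neuron_class: pyramidal
- name: LApv
  tau: 12.0
  tonic: 1.325
  phi: 80.0
  psi: 0.3
  polarity: inhibitory
  neuron_class: parvalbumin
- name: LAvip
  tau: 12.0
  tonic: 0.325
  phi: 60.0
  psi: 0.5
  polarity: inhibitory
  neuron_class: vip
- name: BAp1
  tau: 25.0
  tonic: 0.075
  phi: 20.0
  psi: 0.7
  polarity: excitatory
  neuron_class: pyramidal
- name: BAp2
  tau: 10.0
  tonic: 0.075
  phi: 20.0
  psi: 0.3
  polarity: excitatory
  neuron_class: pyramidal
- name: BAp3
  tau: 25.0
  tonic: 0.075
  phi: 20.0
  psi: 0.5
  polarity: excitatory
  neuron_class: pyramidal
- name: BAp4
  tau: 25.0
  tonic: 0.075
  phi: 20.0
  psi: 0.7
  polarity: excitatory
  neuron_class: pyramidal
- name: BAp5
  tau: 25.0
  tonic: 0.075
  phi: 20.0
  psi: 0.7
  polarity: excitatory
  neuron_class: pyramidal
- name: BAcck
  tau: 10.0
  tonic: 1.325
  phi: 110.0
  psi: 1.666
  polarity: inhibitory
  neuron_class: cck
- name: BApv
  tau: 12.0
  tonic: 1.325
  phi: 80.0
  psi: 1.0
  polarity: inhibitory
  neuron_class: parvalbumin
- name: CeLon
  tau: 15.0
  tonic: 0.325
  phi: 40.0
  psi: 1.2
  polarity: inhibitory
  neuron_class: other
- name: CeLoff
  tau: 15.0
  tonic: 0.325
  phi: 40.0
  psi: 0.0
  polarity: inhibitory
  neuron_class: other
- name: CeM
  tau: 18.0
  tonic: 0.325
  phi: 40.0
  psi: 0.3
  polarity: inhibitory
  neuron_class: other
- name: ITC
  tau: 15.0
  tonic: 0.325
  phi: 30.0
  psi: 1.52
  polarity: inhibitory
  neuron_class: other
- name: PLp
  tau: 25.0
  tonic: 0.075
  phi: 30.0
  psi: 0.3
  polarity: excitatory
  neuron_class: pyramidal
- name: PLpv
  tau: 12.0
  tonic: 1.325
  phi: 80.0
  psi: 0.3
  polarity: inhibitory
  neuron_class: parvalbumin
- name: PLs
  tau: 15.0
  tonic: 0.325
  phi: 30.0
  psi: 0.6
  polarity: inhibitory
  neuron_class: somatostatin
- name: ILp
  tau: 10.0
  tonic: 0.075
  phi: 20.0
  psi: 0.1
  polarity: excitatory
  neuron_class: pyramidal
- name: ILpv
  tau: 35.6
  tonic: 1.325
  phi: 80.0
  psi: 0.3
  polarity: inhibitory
  neuron_class: parvalbumin
- name: ILs
  tau: 15.0
  tonic: 0.325
  phi: 30.0
  psi: 0.1
  polarity: inhibitory
  neuron_class: somatostatin
connections:
- pre: CS
  post: LAp1
  weight: 0.00795
  plasticity:
    rule: LTP
    eta: 0.0003
    M: 0.02385
    sigma: 0.5
- pre: CS
  post: LAp2
  weight: 0.025
- pre: US
  post: LAp1
  weight: 0.02135
- pre: US
  post: LAvip
  weight: 0.03
- pre: LAvip
  post: LApv
  weight: 0.04
- pre: LApv
  post: LAp1
  weight: 0.004
- pre: LApv
  post: LAp2
  weight: 0.018
- pre: LAp1
  post: BAp1
  weight: 7.0
- pre: LAp1
  post: BAp2
  weight: 5.0
- pre: LAp1
  post: BAp5
  weight: 3.0
- pre: LAp1
  post: BAcck
  weight: 0.1336
- pre: BAcck
  post: BAp1
  weight: 0.7
- pre: BAcck
  post: BAp2
  weight: 0.7
  plasticity:
    rule: DSI
    eta: 4.2e-08
- pre: LAp2
  post: CeLon
  weight: 0.06
  plasticity:
    rule: LTP
    eta: 0.0001
    M: 0.18
    sigma: 0.05
- pre: CeLon
  post: CeLoff
  weight: 0.05
- pre: CeLoff
  post: CeM
  weight: 0.19
- pre: BAp1
  post: PLp
  weight: 0.04
- pre: BAp1
  post: PLs
  weight: 0.1
- pre: PLs
  post: PLpv
  weight: 0.1
- pre: PLpv
  post: PLp
  weight: 0.03
- pre: PLp
  post: BApv
  weight: 0.02
- pre: BApv
  post: BAp4
  weight: 0.01
- pre: PLp
  post: BAp4
  weight: 0.1
  plasticity:
    rule: LTP_LTD
    eta: 1.0e-05
    eta_ltd: 6.0e-06
    M: 0.3
    sigma: 0.2
- pre: PLp
  post: ILp
  weight: 0.0044
- pre: BAp2
  post: ILp
  weight: 0.15
  plasticity:
    rule: LTP_LTD
    eta: 3.8e-08
    eta_ltd: 0.0022
    M: 0.45
    sigma: 0.05
- pre: ILs
  post: ILpv
  weight: 0.136
- pre: ILpv
  post: ILp
  weight: 0.0545
- pre: US
  post: ILpv
  weight: 0.007
- pre: ILp
  post: BAp3
  weight: 0.1
- pre: ILp
  post: ITC
  weight: 0.15
- pre: BAp3
  post: ITC
  weight: 0.04
  plasticity:
    rule: LTP
    eta: 5.4e-07
    M: 0.12
    sigma: 0.1
- pre: ITC
  post: BAp4
  weight: 0.18
- pre: BAp4
  post: CeM
  weight: 0.0924
  plasticity:
    rule: DSE
    eta: 9.9e-06
- pre: BAp5
  post: CeM
  weight: 0.054
  plasticity:
    rule: DSE
    eta: 7.6e-06
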