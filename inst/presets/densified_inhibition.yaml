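n_exc: 4000
n_inh: 1000
gamma: 1.0
gamma_scope: both
dt: 0.2
master_seed: 1
neurons:
  excitatory:
    kind: excitatory
    tau_m: 23.3
    capacitance: 0.26
    e_leak: -57.8
    v_thresh: -45.2
    slope: 1.2
    v_reset: -57.8
    v_cut: -33.2
  inhibitory:
    kind: inhibitory
    tau_m: 11.65
    capacitance: 0.13
    e_leak: -57.8
    v_thresh: -45.2
    slope: 1.2
    v_reset: -57.8
    v_cut: -33.2
refractory:
  excitatory:
    mode: soft
    v_thresh:
      amplitude:
      - 22.9
      - 13.5
      tau:
      - 14.7
      - 76.2
    slope:
      amplitude: 10.0
      tau: 17.7
    inv_tau_m:
      amplitude: 0.14
      tau: 14.3
  inhibitory:
    mode: hard
    refractory_period: 2.0
synapses:
  ampa_on_excitatory:
    class: AMPA
    target: excitatory
    tau_r: 1.0
    tau_d: 3.0
    g: 1.0
    e_rev: 0.0
    reference_psp: 0.84
  ampa_on_inhibitory:
    class: AMPA
    target: inhibitory
    tau_r: 1.0
    tau_d: 3.0
    g: 1.5
    e_rev: 0.0
    reference_psp: 2.07
  gaba_on_excitatory:
    class: GABA
    target: excitatory
    tau_r: 1.0
    tau_d: 4.0
    g: 4.0
    e_rev: -75.1
    reference_psp: 1.13
  gaba_on_inhibitory:
    class: GABA
    target: inhibitory
    tau_r: 1.0
    tau_d: 2.0
    g: 4.0
    e_rev: -75.1
    reference_psp: 1.36
  nmda_on_excitatory:
    class: NMDA
    target: excitatory
    tau_r: 3.0
    tau_d: 80.0
    g: 0.14
    e_rev: 0.0
    reference_psp: 0.5
  nmda_on_inhibitory:
    class: NMDA
    target: inhibitory
    tau_r: 3.0
    tau_d: 80.0
    g: 0.21
    e_rev: 0.0
    reference_psp: .na.real
pathways:
- source_layer: both
  source_pop: excitatory
  target_layer: same
  target_pop: excitatory
  p0: 0.06
  p1: 0.06
  latency: 1.0
  interlayer: no
- source_layer: both
  source_pop: excitatory
  target_layer: same
  target_pop: inhibitory
  p0: 0.06
  p1: 0.06
  latency: 1.0
  interlayer: no
- source_layer: both
  source_pop: inhibitory
  target_layer: same
  target_pop: excitatory
  p0: 0.6
  p1: 0.3
  latency: 1.0
  interlayer: no
- source_layer: both
  source_pop: inhibitory
  target_layer: same
  target_pop: inhibitory
  p0: 0.6
  p1: 0.3
  latency: 1.0
  interlayer: no
- source_layer: upper
  source_pop: excitatory
  target_layer: lower
  target_pop: excitatory
  p0: 0.06
  p1: 0.18
  latency: 3.0
  interlayer: yes
- source_layer: upper
  source_pop: excitatory
  target_layer: lower
  target_pop: inhibitory
  p0: 0.06
  p1: 0.18
  latency: 3.0
  interlayer: yes
- source_layer: lower
  source_pop: excitatory
  target_layer: upper
  target_pop: excitatory
  p0: 0.06
  p1: 0.18
  latency: 1.0
  interlayer: yes
- source_layer: lower
  source_pop: excitatory
  target_layer: upper
  target_pop: inhibitory
  p0: 0.07
  p1: 0.16
  latency: 1.0
  interlayer: yes
- source_layer: upper
  source_pop: inhibitory
  target_layer: lower
  target_pop: excitatory
  p0: 0.3
  p1: 0.0
  latency: 3.0
  interlayer: yes
- source_layer: upper
  source_pop: inhibitory
  target_layer: lower
  target_pop: inhibitory
  p0: 0.3
  p1: 0.0
  latency: 3.0
  interlayer: yes
- source_layer: lower
  source_pop: inhibitory
  target_layer: upper
  target_pop: excitatory
  p0: 0.3
  p1: 0.0
  latency: 1.0
  interlayer: yes
- source_layer: lower
  source_pop: inhibitory
  target_layer: upper
  target_pop: inhibitory
  p0: 0.3
  p1: 0.0
  latency: 1.0
  interlayer: yes
lgn:
  g_lgn: 1.0
  rate_offset: 150.0
  rate_gain: 2850.0
  single_cell_dark_rate: 5.0
  single_cell_max_rate: 48.0
  tuning_broadness: 1.0
  lower_layer_attenuation: 0.5
background:
  g_bg: 10.0
  mean_rate: 10.0
  volatility: 1.0
  filter_time: 10.0
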