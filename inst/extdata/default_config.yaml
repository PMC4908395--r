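# Default in-silico study: wild type and the two Tyr215 variants at pH 6.5,
# with the published stopped-flow constants as generating truths.
seed: 20160615
reference: wild-type
instrument:
  dead_time_s: 1.5e-3
  sample_interval_s: 5.0e-4
  noise_sd_AU: 1.0e-3
designs:
  reduction:
    e0_uM: 5.0
    lactate_mM: [0.25, 0.5, 1.0, 2.0, 5.0, 10.0]
  reoxidation:
    e0_uM: 5.0
    o2_uM: [60.0, 125.0, 250.0, 500.0]
  rate_table:
    e0_nM: 50.0
    lactate_mM: [0.05, 0.1, 0.2, 0.5, 1.0, 2.0, 5.0, 10.0]
    o2_uM: 250.0
    replicates: 3
    noise_cv: 0.03
variants:
  - label: wild-type
    ph: 6.5
    rates:
      kd_mM: 1.0
      k3_per_s: 270.0
      k5_per_s: 141.0
      k7_per_M_per_s: 1.8e6
  - label: Y215F
    ph: 6.5
    rates:
      kd_mM: 0.28
      k3_per_s: 120.0
      k5_per_s: 20.0
      k7_per_M_per_s: 7.0e5
  - label: Y215H
    ph: 6.5
    rates:
      kd_mM: 0.55
      k3_per_s: 8.2
      k5_per_s: 26.0
      k7_per_M_per_s: 1.0e5
    optics:
      eps530_E_red_P_per_M_cm: 0.0
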