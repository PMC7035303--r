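# Demo pipeline configuration: seven-segment flow simulation with an ICA
# phantom, pulsatility metrics, a synthetic cohort and the model battery.
seed: 42
log_level: info
stages:
  simulate_flow: true
  metrics: true
  simulate_cohort: true
  analyze: true
flow:
  n_phases: 20
  n_beats: 40
  n_acq: 4000
  phantom:
    enabled: true
    length_mm: 8
    radius: 2.5
    voxel_size: 0.5
    venc: 110
  segments:
    - {artery: ICA, side: left,  mean_flow: 4.5, pulse_amplitude: 5.0, rr_interval: 0.9}
    - {artery: ICA, side: right, mean_flow: 4.3, pulse_amplitude: 4.8, rr_interval: 0.9}
    - {artery: M1,  side: left,  mean_flow: 2.4, pulse_amplitude: 2.7, rr_interval: 0.9}
    - {artery: M1,  side: right, mean_flow: 2.3, pulse_amplitude: 2.6, rr_interval: 0.9}
    - {artery: M3,  side: left,  mean_flow: 1.0, pulse_amplitude: 1.6, peak_width: 0.07, dicrotic_amplitude: 0.3, rr_interval: 0.9}
    - {artery: M3,  side: right, mean_flow: 1.0, pulse_amplitude: 1.5, peak_width: 0.07, dicrotic_amplitude: 0.3, rr_interval: 0.9}
    - {artery: BA,  side: midline, mean_flow: 1.6, pulse_amplitude: 1.6, rr_interval: 0.9}
cohort:
  n_subjects: 300
analysis:
  terms: [ICA_PI, M1_PI, ICA_FVP, M1_FVP]
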