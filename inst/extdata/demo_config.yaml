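# Demonstration configuration for run_pipeline(): a small DWI phantom, one
# water-suppressed / unsuppressed FID pair, and the four-arm longitudinal
# cohort at the study's group sizes. All randomness derives from `seed`.
seed: 20260925
phantom:
  snr_b0: 40
spectrum:
  snr: 50
mrs:
  model_order: 25
  lb: 5
  n_out: 4196
  crlb_threshold: 0.20
stats:
  baseline_day: 0
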