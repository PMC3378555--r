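# Example pipeline configuration (see ?readRunConfig for the defaults and
# the meaning of every field).  Amplitudes are in the simulator's signal
# units; delay amplitudes may be scalars, per-area maps, or per-instruction
# maps of either.
n_subjects: 10
n_per_area: 160
seed: 1
volume_ms_task: 1500
noise_sd: 1.0
between_subject_sd: 0.1
effects:
  amp_s1: 1.5
  amp_s2: 1.5
  delay_match_amp:
    categorical: {V1: 0.0, V2: 0.15, V3: 0.3}
    coordinate: 0.1
  delay_mismatch_amp:
    categorical: 0.0
    coordinate: 0.1
  ecc_amp: 0.1
  ar1_rho: 0.3
  drift: [0.5, 0.5]
  mapping_amp: 3.0
behavior:
  acc: {categorical: 0.95, coordinate: 0.80}
  rt_mean: {categorical: 900, coordinate: 1080}
  rt_sd: {categorical: 180, coordinate: 230}
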