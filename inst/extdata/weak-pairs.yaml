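# Weakly focused beam (waist 12.6 um) imaging pairs of scatterers separated
# by 12 um: unresolved before filtering, resolved after 4x super-refocusing.
grid:
  n_x: 192
  dx_um: 0.75
spectrum:
  lambda0_um: 0.85
  fractional_bandwidth: 0.0257324
  n_k: 32
beam:
  kind: gaussian
  W0_um: 12.6
  z0_um: 252
scene:
  kind: pair_chain
  n_pairs: 7
  separation_um: 12
  z_min_um: 24
  z_max_um: 480
pad_factor: 4
noise:
  snr_db: 30
  seed: 1
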