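# Highly focused Gaussian beam imaging a vertical seven-scatterer chain:
# only the scatterer at the focus depth (252 um) is sharply resolved until
# the volume is digitally refocused.
grid:
  n_x: 256
  dx_um: 0.75
spectrum:
  lambda0_um: 0.85
  fractional_bandwidth: 0.0257324   # conjugate depth step 4 um at pad 4
  n_k: 32
beam:
  kind: gaussian
  WL_um: 35.9          # 1/e amplitude radius at the aperture (waist ~1.9 um)
  z0_um: 252
scene:
  kind: chain
  n_scatterers: 7
  z_min_um: 24
  z_max_um: 480
propagator: paraxial
pad_factor: 4
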