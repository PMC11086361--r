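# The focused chain acquired through a 60 rad coma (Zernike Z_3^1) at the
# aperture; pair with the correct-aberrations subcommand.
grid:
  n_x: 128
  dx_um: 0.75
spectrum:
  lambda0_um: 0.85
  fractional_bandwidth: 0.0257324
  n_k: 32
beam:
  kind: gaussian
  WL_um: 35.9
  z0_um: 252
  aberration:
    Ra_um: 71.8
    terms:
      - {"n": 3, "m": 1, A0_rad: 60}
scene:
  kind: chain
  n_scatterers: 7
  z_min_um: 24
  z_max_um: 480
propagator: full
pad_factor: 4
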