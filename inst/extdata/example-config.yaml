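# Label-and-chase simulation at the headline kinetics: 15 min of light
# (fluorescent) insertion followed by 75 min of dark insertion, doubling
# time fixed at 90 min (which constrains tau to ~50 s).
geometry:
  R: 0.5          # cylinder radius, um
  length: 2       # initial cylindrical length, um
kinetics:
  k_on: 0.004     # event initiations per um^2 per s
  k_ins: 0.00064  # um^2 of membrane added per s per active event
  t_double: 5400  # s; tau is derived from the growth law
schedule:
  light: 900      # s
  dark: 4500      # s
output:
  t_max: 5400
  snapshot_times: [900, 5400]
numerics:
  dt_max: 0.5     # s
  n_images: 21
seed: 1
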