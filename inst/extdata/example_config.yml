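# Example nucpull configuration. Every key is optional; omitted keys use
# the package defaults documented in the corresponding constructor.
mechanics:
  persistence_length: 45    # nm
  stretch_modulus: 1200     # pN
geometry:
  total_bp: 409
  outer_wrap_bp: 62
  inner_wrap_bp: 85
instrument:
  amp1: 28                  # pN
  decay1: 0.35              # mm
acquisition:
  sampling_rate: 500        # Hz (calibration recordings)
  ramp_speed: 10            # um/s
protocol:
  n_cycles: 3
  hold_force: 0.1           # pN
  hold_time: 300            # s
analysis:
  min_jump: 8               # nm
  noise_z_threshold: 4
presets:
  h33_fact:
    transitions:
      - {}                  # outer wrap: keep registry target
      - target_mean: 24.5   # pN, inner wrap
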