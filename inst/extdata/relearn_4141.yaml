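# Four-segment transition history: adapt to 4 g, readapt to 1 g, readapt
# to 4 g. The two later transitions return to previously learned levels.
scenario:
  motion:
    type: roll_tilt
    duration: 400
    freq: 1.0          # rad/s (0.159 Hz)
    peak_velocity: 10  # deg/s -> 10 deg peak roll
  gravity:
    - {start: 0,   level: 1}
    - {start: 100, level: 4}
    - {start: 200, level: 1}
    - {start: 300, level: 4}
engine:
  n_particles: 100
  noise_power: 1.0e-8
  ltm_enabled: true
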