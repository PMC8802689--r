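# Demonstration run: a small synthetic cohort exercised through the whole
# pipeline (epoch-level preprocessing, wave metrics, audiogram, binaural
# series, statistics).  Deterministic for a fixed seed.
seed: 17
cohort:
  n_per_group: 2
  mode: epoch
  n_reps: 30
conditions:
  clicks: true
  click_level_db: 90
  itds: [-1.0, 0.0, 1.0]
  frequencies_khz: [8, 32]
  levels_db: [90, 80, 70, 60, 50, 40, 30, 20]
effects:
  wave4_amp_multiplier:
    "female:Fmr1": 0.7
  animal_sd_av: 0.1
noise:
  background_sd_av: 1.0
  artifact_rate: 0.05
  artifact_amplitude_av: 20
preprocessing:
  filter: true
  low_hz: 50
  high_hz: 3000
  order: 2
audiometry:
  criterion_multiple: 2
  method: template
binaural:
  half_window_ms: 1.5
  noise_floor_multiple: 3
stats: true
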