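# Demo pipeline run: default forearm phantom plus two synthetic tensile
# curves at CB-like magnitudes. Completes in well under two minutes.
seed: 42
pipeline:
  slab_width: 0.2
  station_step: 0.05
  preload: 0.5
  failure_stop_fraction: 0.95
phantom:
  mesh_resolution: 1
  pose: canonical
  truth: {}
tensile:
  synthetic:
    - ligament_id: CB
      specimen_id: demo-1
      stiffness: 43.53
      first_peak_force: 127.80
      ultimate_force: 187.93
      ultimate_strain: 4.40
      gauge_length: 300
      noise_sd: 0
    - ligament_id: CB
      specimen_id: demo-2
      stiffness: 27.71
      first_peak_force: 132.60
      ultimate_force: 196.57
      ultimate_strain: 3.80
      gauge_length: 300
      noise_sd: 1.5
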