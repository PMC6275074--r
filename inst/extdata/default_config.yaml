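# Default experiment configuration for the mango impact-damage pipeline.
# Values mirror default_config(); a user file read with read_config() only
# needs the entries it overrides.
simulation:
  heights: [0.0, 0.5, 1.0, 1.5]   # drop heights in m; 0 = undropped control
  days: [1, 3, 5]                 # measurement days after impact
  n_fruits: 20                    # fruits per (height, day) group
  noise_sd: 0.003                 # additive absorbance noise per band (AU)
  slope_sd: 0.04                  # multiplicative scatter slope sd
  offset_sd: 0.02                 # additive scatter offset sd (AU)
  firmness_units: N
data:
  quality_csv: null               # set both to load measured data instead
  spectra_csv: null
preprocessing:
  method: snv                     # snv | sg | msc | none
  sg_window: 11
  sg_polyorder: 2
regression:
  attributes: [firmness, tss, ta, chroma]
  split_ratio: 0.6                # 3/5 calibration, 2/5 validation
  max_components: 10
  mode: per_group                 # per_group | pooled
cars:
  enabled: true
  n_runs: 50                      # Monte-Carlo sampling runs
  mc_ratio: 0.8                   # fraction of calibration samples per run
  ncomp: 5                        # PLS components inside CARS
classification:
  enabled: true
  slight_min: 7.0                 # RPI above this: slight damage
  serious_max: 5.0                # RPI below this: serious damage
  split_ratio: 0.75               # 3/4 training, 1/4 testing
  cars_attribute: rpi             # response for the feature-selection CARS
instrument:
  n_bands: 256
  wl_min: 900.0                   # nm
  wl_max: 1700.0                  # nm
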