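# Default end-to-end configuration: three imaging conditions of a paired
# intravital design, quantified for soma volume and vessel contact.
seed: 1
voxel: {dx: 0.144, dy: 0.144, dz: 0.988}
simulate:
  shape: [64, 128, 128]
  n_subjects: 3
  save_stacks: false
  params:
    n_vessels: 1
    vessel_radius_um: 4
    n_cells: 3
    crosstalk: 0.3
    background: 20
    foreground: 210
    noise_sd: 38
  conditions:
    - {label: control, coverage_fraction: 0.20, soma_volume_range: [200, 400]}
    - {label: lps_d4, coverage_fraction: 0.12, soma_volume_range: [300, 600]}
    - {label: lps_d8, coverage_fraction: 0.16, soma_volume_range: [250, 500]}
analyses: [soma, contact]
soma:
  threshold_method: renyi
  opening_radii: [5.5, 5.5, 2]
  min_volume: 200
  min_mean_intensity: 60
  max_flatness: 3.5
  watershed_h: 1
contact:
  gaussian_sigma: 2
  saturation: 0.7
  threshold_method: otsu
  crosstalk: after
aqp4:
  contact_distance: 1
  sigma: 1
report:
  baseline: control
  paired: true
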