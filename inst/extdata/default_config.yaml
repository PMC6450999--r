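seg:
  gaussian_sigma: 2.0
  median_radius: 1.0
  thresholds:
    default:
      method: otsu
  pyknotic_threshold:
    method: fixed
    value: 0.6
  pyknotic_dilate: 2.0
  min_component_size: 100.0
  max_nucleus_size: 10000.0
  min_nucleus_size: 30.0
  watershed_h: 2.0
  connectivity: 8.0
  th_small_removal: no
skeleton:
  prune: 3.0
scoring:
  ring_width: 3.0
  min_fraction: 0.01
  nuclear_markers:
  - foxa2
  - sox2
  min_cells: 10.0
stats:
  features:
  - th_foxa2_px_fraction
  - n_nodes
  - foxa2_not_th_px_fraction
  factors:
  - group
  - day
  double_positive_mode: pixel
mode: mip
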