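# Default coronary morphometry statistics, Strahler orders 6-11.
# Per-order radii/lengths emulate porcine casting morphometry at the scale of the
# large-animal literature; the human_scale diameter multiplier is calibrated so that
# the order-11 (main coronary) radius is 1.6 mm (diameter 3.2 mm) after scaling.
# All lengths in mm, viscosity in Pa.s.
orders:
  - order: 6
    mean_radius_mm: 0.0824
    mean_segment_length_mm: 1.0
    sd_segment_length_mm: 0.35
    segments_per_element: 2.0
  - order: 7
    mean_radius_mm: 0.1424
    mean_segment_length_mm: 1.6
    sd_segment_length_mm: 0.55
    segments_per_element: 2.5
  - order: 8
    mean_radius_mm: 0.2464
    mean_segment_length_mm: 2.6
    sd_segment_length_mm: 0.9
    segments_per_element: 3.0
  - order: 9
    mean_radius_mm: 0.4264
    mean_segment_length_mm: 4.2
    sd_segment_length_mm: 1.4
    segments_per_element: 3.0
  - order: 10
    mean_radius_mm: 0.7392
    mean_segment_length_mm: 7.0
    sd_segment_length_mm: 2.4
    segments_per_element: 3.5
  - order: 11
    mean_radius_mm: 1.2800
    mean_segment_length_mm: 14.0
    sd_segment_length_mm: 4.0
    segments_per_element: 10.0
# connectivity[m][n]: expected number of order-n daughter elements per order-m
# parent element. Each element ends in two order-(m-1) daughters; the excess over
# 2 at n = m-1, plus all entries at lower n, are side branches spawned at internal
# junctions (one per junction, so each row's side-branch total equals
# segments_per_element(m) - 1).
connectivity:
  "7":  {"6": 3.5}
  "8":  {"6": 1.4, "7": 2.6}
  "9":  {"6": 0.8, "7": 0.7, "8": 2.5}
  "10": {"6": 0.5, "7": 0.6, "8": 0.8, "9": 2.6}
  "11": {"6": 1.0, "7": 1.5, "8": 2.0, "9": 2.5, "10": 4.0}
length_bounds_mm:
  rca_min: 120.0
  rca_max: 192.0
  left_min: 100.0
  left_max: 160.0
viscosity_pa_s: 3.6e-3
human_scale: [1.25, 1.25, 1.25, 1.25, 1.25, 1.25]
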