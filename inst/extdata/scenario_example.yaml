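# Example defect scenario: idealized medial tibial compartment, two-peak
# stance loading scaled to 71 kg body weight, clinically sized defect
# (5.2 mm^2 footprint, 63% normalized depth) at the compartment center.
compartment:
  plateau_extent_mm: [16, 16]
  target_element_size_mm: 1.5
  thickness_base_mm: 2.0
  thickness_gradient_mm_per_mm: [0.05, 0]
  thickness_bump_mm: 0.6
gait:
  body_mass_kg: 71
  n_time_points: 21
defect:
  footprint_area_mm2: 5.2
  depth_fraction: 0.63
  shape: circular
locations:
  - [0, 0]
submodel:
  extent_mm: 6
  element_size_mm: 0.3
roi_radius_mm: 1.0
seed: 1
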