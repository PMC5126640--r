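# Default cartilage material card (units in key names; moduli MPa,
# permeability mm^4/(N s)). Literature-informed fibril-reinforced
# poroelastic constants for human knee cartilage.
frpe:
  matrix_E_MPa: 0.31
  matrix_nu: 0.42
  permeability_mm4_per_Ns: 2.0e-3
  fibril_E0_MPa: 0.47
  fibril_Eeps_MPa: 150
  primary_density_fraction: 0.75
  n_secondary: 13
  superficial_fraction: 0.15
  deep_fraction: 0.70
meniscus:
  E_circumferential_MPa: 120
  E_transverse_MPa: 20
  G_MPa: 50
  nu_in_plane: 0.3
  nu_out_of_plane: 0.3
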