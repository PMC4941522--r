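# Example run configuration for the forward-model concentration sweep of a
# bend+stiffen protein on the 685-bp TPM tether. All omitted keys take the
# documented defaults (see ?load_config).
kind: sweep
seed: 1
output_dir: archdna_out

polymer:
  persistence_length_nm: 47.2
  contour_length_um: 16.4
  stretch_modulus_pN: 1200

tether:
  dna_length_bp: 685
  segment_length_nm: 5
  bead_radius_nm: 230

binding:
  mode: stiffen        # bend in cis at low coverage, filament above onset
  footprint_bp: 25
  bend_angle_deg: 60
  filament_lp_nm: 61
  unwind_factor: 0.1

isotherm:
  kd_nM: 1
  footprint_bp: 25
  omega: 1
  stiffening_onset: 0.878
  onset_width: 0.04
  salt_label: "100 mM NaCl"

sweep:
  concentrations_nM: [0, 1, 5, 20, 50, 100, 500, 1000, 3000]
  n_samples: 4000
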