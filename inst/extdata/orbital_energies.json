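[
  {"label": "complex_1", "e_homo_eV": -4.24, "e_lumo_eV": -2.69, "dipole_D": 0.29},
  {"label": "complex_2", "e_homo_eV": -5.39, "e_lumo_eV": -2.66, "e_somo_eV": -4.06, "dipole_D": 1.04}
]
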