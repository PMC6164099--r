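# Optical constants at 632.8 nm (HeNe line). Complex refractive index n + ik.
wavelength_nm: 632.8
materials:
  bk7:
    n_real: 1.510
    n_imag: 0.0
  silver:
    n_real: 0.13455
    n_imag: 3.98651
  water:
    n_real: 1.33
    n_imag: 0.0
  air:
    n_real: 1.0
    n_imag: 0.0
  blood_plasma:
    n_real: 1.3479
    n_imag: 0.0
  hb_cytoplasm:
    n_real: 1.3800
    n_imag: 0.0
  hb_cytoplasm_concentrated:
    # 12.93 mmol/L haemoglobin solution
    n_real: 1.3871
    n_imag: 0.0
  lecithin:
    n_real: 1.4838
    n_imag: 0.0
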