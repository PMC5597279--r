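{
  "mandible_components": {
    "material": ["Cortical bone-symphysis region", "Cortical bone-angle region",
                 "Cortical bone-rest of mandible", "Cancellous bone",
                 "Cortical-fibular graft", "Cancellous-fibular graft",
                 "Teeth", "Periodontal ligament", "Ti-6Al-4V", "NiTi"],
    "Ex_MPa": [23000, 20000, 17000, 960, 26800, 1650, 17600, 2.7, 112000, 37000],
    "Ey_MPa": [15000, 12000, 8200, 390, 26800, 1650, 17600, 2.7, 112000, 37000],
    "Ez_MPa": [10000, 11000, 6900, 320, 26800, 1650, 17600, 2.7, 112000, 37000],
    "nu_xy": [0.3, 0.3, 0.315, 0.3, 0.3, 0.3, 0.25, 0.45, 0.3, 0.3],
    "nu_yz": [0.3, 0.3, 0.325, 0.3, 0.3, 0.3, 0.25, 0.45, 0.3, 0.3],
    "nu_xz": [0.3, 0.3, 0.31, 0.3, 0.3, 0.3, 0.25, 0.45, 0.3, 0.3]
  },
  "compression_test": {
    "material": ["NiTi", "Ti-6Al-4V"],
    "E_GPa": [37, 112],
    "yield_MPa_low": [1011, 970],
    "yield_MPa_high": [1011, 1030]
  },
  "niti_superelastic": {
    "E_A": 37, "E_M": 42, "nu": 0.33,
    "Ms": 263, "Mf": 243, "As": 270, "Af": 280,
    "C_M": 7, "C_A": 7, "H": 0.04,
    "sigma_y": 1011, "T_op": 310
  }
}
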