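{
  "comment": "Electronic level diagram of the meta-HBDI anion and its neutral radical. Energies in eV relative to the anion S0 minimum; provenance distinguishes measured (photoelectron spectroscopy) from calculated (XMCQDPT2) values. MECI heights are relative to the S1 minimum.",
  "states": [
    {
      "label": "S0",
      "species": "anion",
      "adiabatic_eV": {"value_eV": 0.0, "provenance": "calculated"}
    },
    {
      "label": "S1",
      "species": "anion",
      "adiabatic_eV": {"value_eV": 1.51, "provenance": "calculated"},
      "vertical_eV": {"value_eV": 1.76, "provenance": "calculated"},
      "oscillator_strength": {"value": 0.03, "provenance": "calculated"},
      "provenance": "calculated"
    },
    {
      "label": "S2",
      "species": "anion",
      "vertical_eV": {"value_eV": 3.2, "provenance": "calculated"},
      "oscillator_strength": {"value": 0.7, "provenance": "calculated"},
      "provenance": "calculated"
    },
    {
      "label": "S6",
      "species": "anion",
      "vertical_eV": {"value_eV": 4.6, "provenance": "calculated"},
      "provenance": "calculated"
    },
    {
      "label": "D0",
      "species": "neutral",
      "adiabatic_eV": {"value_eV": 2.30, "provenance": "measured"},
      "vertical_eV": {"value_eV": 2.63, "provenance": "measured"},
      "provenance": "measured"
    },
    {
      "label": "D1n",
      "species": "neutral",
      "vertical_eV": {"value_eV": 3.58, "provenance": "calculated"},
      "provenance": "calculated"
    }
  ],
  "vde_d0": [
    {"value_eV": 2.63, "provenance": "measured"},
    {"value_eV": 2.54, "provenance": "calculated"}
  ],
  "ade_d0": [
    {"value_eV": 2.30, "provenance": "measured"}
  ],
  "vde_d1n": [
    {"value_eV": 3.58, "provenance": "calculated"}
  ],
  "meci": {
    "s1_s0": {"value_eV": 0.41, "reference": "S1_minimum", "provenance": "calculated"},
    "s2_s0": {"value_eV": 0.55, "reference": "S1_minimum", "provenance": "calculated"}
  }
}
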