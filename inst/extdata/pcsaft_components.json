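[
  {
    "name": "acetylsalicylic acid",
    "m": 5.583,
    "sigma": 3.8593,
    "eps_k": 256.38,
    "kappa_ab": 0.01,
    "eps_ab_k": 2453.8,
    "assoc_scheme": "2B",
    "molar_mass": 180.16,
    "_row": "asa"
  },
  {
    "name": "ethanol",
    "m": 2.3827,
    "sigma": 3.1771,
    "eps_k": 198.2,
    "kappa_ab": 0.032384,
    "eps_ab_k": 2653.4,
    "assoc_scheme": "2B",
    "molar_mass": 46.07,
    "_row": "ethanol"
  },
  {
    "name": "water",
    "m": 1.0656,
    "sigma": 3.0007,
    "eps_k": 366.51,
    "kappa_ab": 0.034868,
    "eps_ab_k": 2500.7,
    "assoc_scheme": "2B",
    "molar_mass": 18.015,
    "_row": "water"
  }
]
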