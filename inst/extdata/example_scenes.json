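[
  {
    "height": 96, "width": 96, "background": "white",
    "noise_sigma": 8, "seed": 5,
    "chromatosomes": [
      {"center": [30, 30], "dispersion_class": 4, "base_radius": 14},
      {"center": [60, 60], "dispersion_class": 5, "base_radius": 14},
      {"center": [30, 70], "dispersion_class": 2, "base_radius": 14}
    ]
  },
  {
    "height": 96, "width": 96, "background": "green",
    "noise_sigma": 6, "seed": 11,
    "chromatosomes": [
      {"center": [25, 40], "dispersion_class": 3, "base_radius": 12},
      {"center": [65, 55], "dispersion_class": 5, "base_radius": 12,
       "rotation": 0.5}
    ]
  }
]
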