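{
  "version": "1.0",
  "note": "Scaffolding values for non-marker carbons in synthetic compounds: typical pyranoxanthone positions, perturbed deterministically per subtype within subtype_spread_ppm and clamped to the per-class ranges.",
  "subtype_spread_ppm": 3,
  "class_ranges": {
    "core_CH": [88, 135],
    "core_Cq": [100, 166],
    "carbonyl": [172, 188],
    "pyran_olefinic_1p": [110, 125],
    "pyran_olefinic_2p": [123, 136],
    "pyran_O_Cq": [138, 162],
    "methyl": [15, 32],
    "methoxy": [55, 62],
    "other": [20, 220]
  },
  "fillers": [
    {
      "label": "C-1",
      "carbon_class": "core_Cq",
      "base_ppm": 160.9
    },
    {
      "label": "C-2",
      "carbon_class": "core_CH",
      "base_ppm": 98.5
    },
    {
      "label": "C-3",
      "carbon_class": "core_Cq",
      "base_ppm": 162.5
    },
    {
      "label": "C-4",
      "carbon_class": "core_CH",
      "base_ppm": 93.5
    },
    {
      "label": "C-4a",
      "carbon_class": "core_Cq",
      "base_ppm": 156.2
    },
    {
      "label": "C-10a",
      "carbon_class": "core_Cq",
      "base_ppm": 151.8
    },
    {
      "label": "C-5",
      "carbon_class": "core_CH",
      "base_ppm": 101.5
    },
    {
      "label": "C-6",
      "carbon_class": "core_Cq",
      "base_ppm": 155.5
    },
    {
      "label": "C-7",
      "carbon_class": "core_CH",
      "base_ppm": 112.5
    },
    {
      "label": "C-8",
      "carbon_class": "core_CH",
      "base_ppm": 125
    },
    {
      "label": "C-8a",
      "carbon_class": "core_Cq",
      "base_ppm": 112.8
    },
    {
      "label": "C-9a",
      "carbon_class": "core_Cq",
      "base_ppm": 103.2
    },
    {
      "label": "C-3'",
      "carbon_class": "other",
      "base_ppm": 78.1
    },
    {
      "label": "CH3-a",
      "carbon_class": "methyl",
      "base_ppm": 28.3
    },
    {
      "label": "CH3-b",
      "carbon_class": "methyl",
      "base_ppm": 28.3
    }
  ]
}
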