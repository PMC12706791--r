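{
  "version": "1.0",
  "scope": "gathered",
  "note": "Gathered-set empirical correction factors (offset = mean(exp - calc), applied as calc + offset). Derivation n/sd refer to the original 76-compound modeling set whose shift lists are not packaged.",
  "factors": [
    {
      "class": "C1_C8",
      "offset_ppm": -2.9,
      "n": null,
      "sd": null,
      "description": "xanthone core C-1 and C-8, pooled (symmetry-equivalent positions flanking the carbonyl)"
    },
    {
      "class": "C1p",
      "offset_ppm": -3.7,
      "n": null,
      "sd": null,
      "description": "pyran olefinic C-1'"
    },
    {
      "class": "C2p",
      "offset_ppm": 2.8,
      "n": null,
      "sd": null,
      "description": "pyran olefinic C-2'"
    }
  ]
}
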