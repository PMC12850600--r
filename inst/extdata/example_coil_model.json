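{
  "ref_radius_mm": 250,
  "coefficients": [
    {
      "axis": "x",
      "degree": 1,
      "order": 1,
      "coefficient": 1
    },
    {
      "axis": "y",
      "degree": 1,
      "order": -1,
      "coefficient": 1
    },
    {
      "axis": "z",
      "degree": 1,
      "order": 0,
      "coefficient": 1
    },
    {
      "axis": "x",
      "degree": 3,
      "order": 1,
      "coefficient": -0.045
    },
    {
      "axis": "x",
      "degree": 5,
      "order": 1,
      "coefficient": 0.012
    },
    {
      "axis": "y",
      "degree": 3,
      "order": -1,
      "coefficient": -0.041
    },
    {
      "axis": "z",
      "degree": 3,
      "order": 0,
      "coefficient": -0.052
    },
    {
      "axis": "z",
      "degree": 5,
      "order": 0,
      "coefficient": 0.015
    }
  ]
}
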