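{
  "name": "C-SED-like",
  "rules": [
    {
      "dmin": 15,
      "action": "DIAG"
    },
    {
      "dmin": 10,
      "growing": true,
      "action": "DIAG"
    },
    {
      "growing": true,
      "action": "F3"
    },
    {
      "dmin": 8,
      "action": "F3"
    },
    {
      "dmax": 8,
      "stages": 3,
      "action": "END"
    },
    {
      "action": "F12"
    }
  ],
  "growth_threshold": 0.00547945205479452,
  "provenance": "synthetic approximation of a China-style size/growth protocol; non-authoritative"
}
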