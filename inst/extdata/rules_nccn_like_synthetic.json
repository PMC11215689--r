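{
  "name": "NCCN-like",
  "rules": [
    {
      "dmin": 15,
      "action": "DIAG"
    },
    {
      "dmin": 8,
      "growing": true,
      "action": "DIAG"
    },
    {
      "growing": true,
      "action": "F3"
    },
    {
      "dmin": 8,
      "spiculated": true,
      "action": "DIAG"
    },
    {
      "dmin": 8,
      "action": "F3"
    },
    {
      "dmin": 6,
      "attenuation": ["part_solid", "non_solid"],
      "action": "F3"
    },
    {
      "dmax": 6,
      "stages": 3,
      "action": "END"
    },
    {
      "action": "F12"
    }
  ],
  "growth_threshold": 0.00410958904109589,
  "provenance": "synthetic approximation of a US-style size/growth protocol; non-authoritative"
}
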