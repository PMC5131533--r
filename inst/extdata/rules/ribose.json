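{
  "sugar": "ribose",
  "name": "ribT or strain-specific mfs9C23 uptake, complemented kinase/isomerase",
  "routes": [
    [
      [
        "ribT"
      ],
      [
        "ribK",
        "ribK1"
      ],
      [
        "ribA",
        "ribA1"
      ]
    ],
    [
      [
        "mfs9C23"
      ],
      [
        "ribK",
        "ribK1"
      ],
      [
        "ribA",
        "ribA1"
      ]
    ]
  ]
}
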