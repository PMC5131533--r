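{
  "sugar": "L-arabinose",
  "name": "arabinose isomerase/kinase/epimerase triad with araD1 rescue",
  "routes": [
    [
      [
        "araA"
      ],
      [
        "araB"
      ],
      [
        "araD",
        "araD1"
      ]
    ]
  ]
}
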