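{
  "sugar": "mannose",
  "name": "manB PTS uptake with phosphomannose isomerase",
  "routes": [
    [
      [
        "manB"
      ],
      [
        "manI"
      ]
    ]
  ]
}
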