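{
  "sugar": "fructose",
  "name": "manC PTS (fructose-6-P) or any pts-fructose cluster (fructose-1-P)",
  "routes": [
    [
      [
        "manC"
      ]
    ],
    [
      [
        "fruA",
        "fruB",
        "fruC",
        "fruD"
      ]
    ]
  ]
}
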