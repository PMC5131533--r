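{
  "sugar": "glucose",
  "name": "PTS-mannose operons or MFS permease plus hexokinase (illustrative)",
  "routes": [
    [
      [
        "manA",
        "manB",
        "manC"
      ]
    ],
    [
      [
        "mfs1574",
        "mfs0819"
      ],
      [
        "nagC",
        "nagC1",
        "nagC2"
      ]
    ]
  ]
}
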