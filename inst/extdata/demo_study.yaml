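seed: 7
simulate: true
n_appearances: 24
drive_types: [city, highway]
participants:
  - id: CFL_demo
    field: field_CFL_demo.json
  - id: NV_demo
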