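{
  "participant_id": "CFL_demo",
  "polygons": [
    [[-7, 8], [-4.2, 3], [4.2, 3], [7, 8], [4.2, 13], [-4.2, 13]]
  ],
  "prl_note": "scotoma above PRL (synthetic demo field)"
}
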