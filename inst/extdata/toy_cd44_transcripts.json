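[
  {
    "transcript_id": "CD44s_like",
    "exon_refs": [
      "e1",
      "e2",
      "e3",
      "e4",
      "e5",
      "e15",
      "e16",
      "e17",
      "e18",
      "e19"
    ],
    "declared_coding": true
  },
  {
    "transcript_id": "CD44v2_10_like",
    "exon_refs": [
      "e1",
      "e2",
      "e3",
      "e4",
      "e5",
      "v2",
      "v3",
      "v4",
      "v5",
      "v6",
      "v7",
      "v8",
      "v9",
      "v10",
      "e15",
      "e16",
      "e17",
      "e18",
      "e19"
    ],
    "declared_coding": true
  },
  {
    "transcript_id": "CD44v3_10_like",
    "exon_refs": [
      "e1",
      "e2",
      "e3",
      "e4",
      "e5",
      "v3",
      "v4",
      "v5",
      "v6",
      "v7",
      "v8",
      "v9",
      "v10",
      "e15",
      "e16",
      "e17",
      "e18",
      "e19"
    ],
    "declared_coding": true
  },
  {
    "transcript_id": "CD44v8_10_like",
    "exon_refs": [
      "e1",
      "e2",
      "e3",
      "e4",
      "e5",
      "v8",
      "v9",
      "v10",
      "e15",
      "e16",
      "e17",
      "e18",
      "e19"
    ],
    "declared_coding": true
  },
  {
    "transcript_id": "CD44sol_like",
    "exon_refs": [
      "e1",
      {
        "exon_id": "e2",
        "start": 0,
        "end": 30
      },
      {
        "exon_id": "e3",
        "start": 36
      },
      "e19"
    ],
    "declared_coding": true
  }
]
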