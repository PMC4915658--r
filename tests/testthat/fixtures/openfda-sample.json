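{
  "meta": {"results": {"skip": 0, "limit": 3, "total": 3}},
  "results": [
    {
      "safetyreportid": "10001",
      "patient": {
        "drug": [
          {
            "medicinalproduct": "VALIUM",
            "drugindication": "ANXIETY",
            "openfda": {"substance_name": ["DIAZEPAM"]}
          },
          {
            "medicinalproduct": "ADVIL PM",
            "openfda": {"substance_name": ["DIPHENHYDRAMINE", "IBUPROFEN"]}
          }
        ],
        "reaction": [
          {"reactionmeddrapt": "SOMNOLENCE"},
          {"reactionmeddrapt": "ABDOMINAL PAIN"}
        ]
      }
    },
    {
      "safetyreportid": "10002",
      "patient": {
        "drug": [
          {"medicinalproduct": "MYSTERY TONIC 500MG"}
        ],
        "reaction": [{"reactionmeddrapt": "RASH"}]
      }
    },
    {
      "safetyreportid": "10003",
      "patient": {
        "drug": [
          {
            "medicinalproduct": "HALDOL",
            "drugindication": "PSYCHOTIC DISORDER",
            "openfda": {"substance_name": ["HALOPERIDOL"]}
          }
        ],
        "reaction": [{"reactionmeddrapt": "RASH"}]
      }
    }
  ]
}
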