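[
  {"safetyreportid": "777", "patient": {"drug": [{"openfda": {"substance_name": ["ASPIRIN"]}}], "reaction": [{"reactionmeddrapt": "TINNITUS"}]}},
  {"patient": {"drug": [{"openfda": {"substance_name": ["WARFARIN"]}}], "reaction": [{"reactionmeddrapt": "EPISTAXIS"}]}},
  {"safetyreportid": "777", "patient": {"drug": [{"openfda": {"substance_name": ["ASPIRIN"]}}], "reaction": [{"reactionmeddrapt": "DYSPEPSIA"}]}}
]
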