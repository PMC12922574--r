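b_values: [0.0, 10.0, 20.0, 100.0, 200.0, 550.0]
te_values: [50.0, 55.0, 60.0, 65.0, 70.0, 75.0, 80.0, 85.0, 90.0, 95.0, 100.0]
tr_values: [4000.0]
reference_te: 50.0
reference_tr: 4000.0
meta:
  description: >
    Six community-consensus liver b-values (CRLB-derived) with the
    extended candidate echo-time range used for protocol design.
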