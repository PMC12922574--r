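b_values: [0.0, 10.0, 20.0, 30.0, 50.0, 70.0, 100.0, 150.0, 200.0, 250.0,
           300.0, 350.0, 450.0, 550.0, 650.0, 750.0]
te_values: [47.0, 52.0, 57.0, 62.0, 67.0, 72.0]
tr_values: [1900.0]
averages: [3, 3, 3, 3, 3, 4, 4, 4, 4, 4, 4, 4, 5, 5, 5, 5]
reference_te: 47.0
reference_tr: 1900.0
meta:
  description: >
    In-vivo-style abdominal protocol: 16 b-values with per-b averages and
    six echo times 47-72 ms in 5 ms steps (monopolar PGSE at 3T).
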