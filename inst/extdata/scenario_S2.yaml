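name: S2
label: fast cultivated-land expansion
demand_source: table
weights_row: S2
conversion: s1s2
restricted: []
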