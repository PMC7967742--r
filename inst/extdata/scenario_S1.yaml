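name: S1
label: business as usual
demand_source: markov
weights_row: S1
conversion: s1s2
restricted: []
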