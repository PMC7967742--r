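name: S4
label: sustainable development
demand_source: table
weights_row: S4
conversion: s3s4
restricted: [redline, farmland]
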