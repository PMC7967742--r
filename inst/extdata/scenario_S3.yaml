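name: S3
label: ecological security
demand_source: table
weights_row: S3
conversion: s3s4
restricted: [redline]
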