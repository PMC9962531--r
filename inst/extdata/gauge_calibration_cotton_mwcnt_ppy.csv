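stretch_mm,coefficient_pct
5,27.49
10,61.93
15,89.89
20,136.91
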