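# 30-min pulse, then washout with receptor-kinase inhibition
dose: 2
exposure: short
t_wash: 30
horizon: 1440
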