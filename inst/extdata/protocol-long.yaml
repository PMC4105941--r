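# Continuous saturating stimulation, 24 hr
dose: 2
exposure: long
horizon: 1440
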