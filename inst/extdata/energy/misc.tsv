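key	value
terminal_au	0.5
ninio	0.6
ninio_max	3
temperature_C	37
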