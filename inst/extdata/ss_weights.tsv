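ss	weight
H	1.0
E	1.0
C	1.0
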