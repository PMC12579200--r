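gene	class	probability
COMBINED	missense	0.3148148148
COMBINED	splice	0.0074404762
COMBINED	synonymous	0.1398880895
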