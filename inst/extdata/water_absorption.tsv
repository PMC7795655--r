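wavelength	mua
700	0.0060
750	0.0262
800	0.0206
850	0.0430
900	0.0679
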