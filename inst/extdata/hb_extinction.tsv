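wavelength	eps_hbr	eps_hbo2
700	1794.28	290.0
730	1102.20	390.0
750	1405.24	518.0
760	1548.52	586.0
800	761.72	816.0
850	691.32	1058.0
900	761.84	1198.0
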