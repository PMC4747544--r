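hotspot	name	class	family
A2	L1MEg	LINE	L1
A2	SINEC-Fc2	SINE	tRNA-Lys
A2	MIR	SINE	MIR
A2	MIRb	SINE	MIR
A2	AT-rich	Low_complexity	Low_complexity
A2	MER46C	DNA	TcMar-Tigger
D1	L2a	LINE	L2
D1	SINEC-Fc2	SINE	tRNA-Lys
D1	MIRb	SINE	MIR
D1	MIRb	SINE	MIR
D1	MLT1J	LTR	ERVL-MaLR
D1	(TA)n	Simple_repeat	Simple_repeat
E2a	L2a	LINE	L2
E2a	MIR3	SINE	MIR
E2b	L2b	LINE	L2
E2b	L2b	LINE	L2
E2b	L2a	LINE	L2
E2b	SINEC-Fc2	SINE	tRNA-Lys
E2b	MIR	SINE	MIR
E2b	(GA)n	Simple_repeat	Simple_repeat
E2b	(TG)n	Simple_repeat	Simple_repeat
E2b	MER20	DNA	hAT-Charlie
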