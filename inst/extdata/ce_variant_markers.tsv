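family	sequence	role	variant_label	genes	pair
H3	YRPGTVALR	canonical	H3	several	1
H3	VTIMPKDIQLAR	canonical	H3	several	2
H3	IRGER	canonical	H3	several	0
H3	FRPGTVALR	variant	H3.3V	his-69;his-74	1
H3	VTIMPKDMQLAR	variant	H3.3V	his-69;his-74;his-72	2
H2A	AGLQFPVGR	canonical	H2A	several	0
H2A	HLQLAVR	canonical	H2A	several	3
H2A	FLKQR	variant	H2AV	htz-1	0
H2A	HLHLAIR	variant	H2AV	htz-1	3
H1	QALKR	variant	H1.0	his-24	0
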