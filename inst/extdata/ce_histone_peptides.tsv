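histone	start	end	sequence	forms
H3	3	8	TKQTAR	unmod; K4me1; K4me2; K4me3; K4ac
H3	9	17	KSTGGKAPR	unmod; K9me1; K9me2; K9me3; K9ac; K14ac; K9me1K14ac; K9me2K14ac; K9me3K14ac; K9acK14ac
H3	9	17	KSTGGKAPR	S10ph; K9me1S10ph; K9me2S10ph; K9me3S10ph; K9acS10ph; S10phK14ac; K9me1S10phK14ac; K9me2S10phK14ac; K9me3S10phK14ac; K9acS10phK14ac
H3	18	26	KQLATKAAR	unmod; K23me1; K18me1; K18me1K23me1; K18ac; K23ac; K18acK23ac; K23me2; K23me3; K18acK23me1; K18acK23me2; K18acK23me3
H3.3V1	18	26	KALATKAAR	unmod; K23me1; K18me1; K18me1K23me1; K18ac; K23ac; K18acK23ac
H3	27	40	KSAPASGGVKKPHR	unmod; K27me1; K27me2; K27me3; K27ac; K36me1; K27me1K36me1; K27me2K36me1; K27me3K36me1; K27acK36me1; K36me2; K27me1K36me2; K27me2K36me2; K27me3K36me2; K27acK36me2; K36me3; K27me1K36me3; K27me2K36me3; K27me3K36me3; K27acK36me3; K36ac; K27me1K36ac; K27me2K36ac; K27me3K36ac; K27acK36ac
H3.3V1	27	40	KSAIVTGSVKKVHR	unmod; K36me1; K27me1; K27me2; K36me2; K27me3; K36me3; K27me2K36me1; K27me1K36me2; K27me1K36me1; K27me3K36me1; K27me1K36me3; K27me2K36me2; K27me3K36me2; K27ac
H3.3V2	27	40	KSAPTTGGVKKPHR	unmod; K27me1; K27me2; K27me3; K27ac; K36me1; K27me1K36me1; K27me2K36me1; K27me3K36me1; K27acK36me1; K36me2; K27me1K36me2; K27me2K36me2; K27me3K36me2; K27acK36me2; K36me3; K27me1K36me3; K27me2K36me3; K27me3K36me3; K27acK36me3; K36ac; K27me1K36ac; K27me2K36ac; K27me3K36ac; K27acK36ac
H3	54	63	YQKSTELLIR	unmod; K56ac
H3	64	69	KLPFQR	unmod; K64ac
H3	73	83	EIAQDFKTDLR	unmod; K79me1; K79me2; K79me3; K79ac
H3	117	128	VTIMPKDIQLAR	unmod; K122ac
H4	4	17	GKGGKGLGKGGAKR	unmod; K5ac; K8ac; K12ac; K16ac; K5acK8ac; K5acK12ac; K5acK16ac; K8acK12ac; K8acK16ac; K12acK16ac; K5acK8acK12ac; K5acK8acK16ac; K5acK12acK16ac; K8acK12acK16ac; K5acK8acK12acK16ac
H4	20	23	KVLR	unmod; K20me1; K20me2; K20me3; K20ac
H4	24	35	DNIQGITKPAIR	unmod; K31ac
H4	40	45	RGGVKR	unmod; K44me1
H4	68	78	DAVTYCEHAKR	unmod; T71ph
H4	79	92	KTVTAMDVVYALKR	unmod; K79ac
H1	90	107	GVTSKALVQAAGSGANGR	unmod; K94me1; K94ac
H2A	4	18	GKGGKAKTGGKAKSR	unmod; K5ac; K8ac; K10ac; K16ac; K5acK8ac; K5acK10ac; K5acK16ac; K8acK10ac; K8acK16ac; K10acK16ac; K8acK10acK16ac; K5acK10acK16ac; K5acK8acK16ac; K5acK8acK10ac; K5acK8acK10acK16ac
H2AV	1	21	AGGKGKAGKDSGKSKSKVVSR	unmod; K4ac; K9ac; K13ac; K17ac; K4acK9ac; K4acK13ac; K4acK17ac; K9acK13ac; K9acK17ac; K13acK17ac; K9acK13acK17ac; K4acK13acK17ac; K4acK9acK17ac; K4acK9acK13ac; K4acK9acK13acK17ac
H2A	37	43	KGNYAQR	unmod; K37ac
H2A	73	78	DNKKTR	unmod; K75ac
H2B	31	40	KESYSVYIYR	unmod; K31me1; K31me2; K31me3; K31ac
H2B	77	83	LAHYNKR	unmod; K82ac
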