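label	histone	start	end	members	mz	z	t_start	t_stop
H3K36me3/K27me2K36me1	H3	27	40	K36me3; K27me2K36me1	543.9860	3	20	40
H3.3K36me3/K27me2K36me1	H3.3V2	27	40	K36me3; K27me2K36me1	558.6674	3	20	40
H3K9ac/K14ac	H3	9	17	K9ac; K14ac	528.2988	2	20	40
H3S10phK14ac/S10phK9ac	H3	9	17	S10phK14ac; K9acS10ph	568.2790	2	25	40
H3K18me1/K23me1	H3	18	26	K18me1; K23me1	584.8561	2	30	50
H2A 4_18 3ac	H2A	4	18	K8acK10acK16ac; K5acK10acK16ac; K5acK8acK16ac; K5acK8acK10ac	862.9863	2	30	50
H2A 4_18 2ac	H2A	4	18	K5acK8ac; K5acK10ac; K5acK16ac; K8acK10ac; K8acK16ac; K10acK16ac	869.9941	2	30	50
H4 4_17 3ac	H4	4	17	K5acK8acK12ac; K5acK8acK16ac; K5acK12acK16ac; K8acK12acK16ac	754.9308	2	30	50
H2A 4_18 1ac	H2A	4	18	K5ac; K8ac; K10ac; K16ac	877.0019	2	30	50
H3K27me1/K36me1	H3	27	40	K27me1; K36me1	829.4728	2	30	50
H3.3L2K36me3/K27me2K36me1	H3.3V1	27	40	K36me3; K27me2K36me1	574.0200	3	30	60
H4 4_17 2ac	H4	4	17	K5acK8ac; K5acK12ac; K5acK16ac; K8acK12ac; K8acK16ac; K12acK16ac	761.9386	2	33	50
H3.3K27me1/K36me1	H3.3V2	27	40	K27me1; K36me1	851.4859	2	35	50
H4 4_17 1ac	H4	4	17	K5ac; K8ac; K12ac; K16ac	768.9465	2	35	55
H2AV 1_21 3ac	H2AV	1	21	K9acK13acK17ac; K4acK13acK17ac; K4acK9acK17ac; K4acK9acK13ac	794.7711	3	35	60
H2AV 1_21 2ac	H2AV	1	21	K4acK9ac; K4acK13ac; K4acK17ac; K9acK13ac; K9acK17ac; K13acK17ac	799.4430	3	40	60
H3K18ac/K23ac	H3	18	26	K18ac; K23ac	570.8404	2	40	60
H2AV 1_21 1ac	H2AV	1	21	K4ac; K9ac; K13ac; K17ac	804.1148	3	40	60
H3.3L2K27me1/K36me1	H3.3V1	27	40	K27me1; K36me1	874.5251	2	50	70
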