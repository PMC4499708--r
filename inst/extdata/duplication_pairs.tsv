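pair	species	ka	ks	ratio	mechanism	t_mya
AtENODL17/AtENODL19	Arabidopsis thaliana	0.18395	0.70102	0.26243	Retrotransposition	23.37
AtENODL3/AtENODL4	Arabidopsis thaliana	0.13741	0.31929	0.43036	Retrotransposition	10.64
AtENODL14/AtENODL15	Arabidopsis thaliana	0.18437	0.70152	0.26282	Segmental duplication	23.38
AtENODL5/AtENODL6	Arabidopsis thaliana	0.22558	0.77783	0.29001	Segmental duplication	25.93
AtUC4/AtUC5	Arabidopsis thaliana	0.31272	0.85669	0.36503	Segmental duplication	28.56
AtENODL1/AtENODL2	Arabidopsis thaliana	0.46645	1.45391	0.32083	Segmental duplication	48.46
AtENODL11/AtENODL12	Arabidopsis thaliana	0.38216	1.36091	0.28081	Segmental duplication	45.36
AtSC1/AtSC2	Arabidopsis thaliana	0.19307	0.34871	0.55367	Retrotransposition	11.63
At1g45063/At3g53330	Arabidopsis thaliana	0.37509	0.71432	0.5251	Retrotransposition	23.81
AtENODL22/AtPC1	Arabidopsis thaliana	0.72483	3.00941	0.24085	Retrotransposition	100.31
AtUC3/AtUC7	Arabidopsis thaliana	0.22650	0.59184	0.3827	Tandem duplication	19.73
ZmUC6/ZmUC10	Zea mays	0.05401	0.18988	0.28444	Segmental duplication	17.26
ZmUC11/ZmUC24	Zea mays	0.32393	0.50672	0.63927	Tandem duplication	46.07
ZmUC13/ZmUC14	Zea mays	0.10750	0.18573	0.57879	Segmental duplication	16.88
ZmUC16/ZmPLC3	Zea mays	0.67658	0.88356	0.76574	Retrotransposition	80.32
ZmUC8/ZmUC19	Zea mays	0.49874	0.74853	0.66629	Retrotransposition	68.05
ZmSC4/ZmSC5	Zea mays	0.02184	0.01847	1.18246	Retrotransposition	1.68
ZmSC1/ZmSC2	Zea mays	0.11703	0.23277	0.50277	Segmental duplication	21.16
ZmUC1/ZmUC12	Zea mays	0.09926	0.15513	0.63985	Tandem duplication	14.10
ZmUC3/ZmUC23	Zea mays	0.40586	0.54119	0.74994	Retrotransposition	41.63
ZmUC18/ZmUC26	Zea mays	0.80249	0.91956	0.87269	Retrotransposition	70.74
ZmENODL20/ZmENODL22	Zea mays	0.64824	0.94528	0.68577	Retrotransposition	85.93
ZmUC22/ZmPLC2	Zea mays	0.43753	0.64158	0.68196	Retrotransposition	58.33
ZmPLC1/ZmUC9	Zea mays	0.05469	0.14448	0.37853	Retrotransposition	13.13
ZmUC4/ZmUC5	Zea mays	0.06773	0.12898	0.52512	Tandem duplication	11.72
ZmENODL2/ZmENODL25	Zea mays	0.56183	0.92832	0.60521	Retrotransposition	84.39
ZmENODL4/ZmENODL19	Zea mays	0.17464	0.33073	0.52804	Segmental duplication	30.07
ZmENODL7/ZmENODL13	Zea mays	0.0335	0.07531	0.44483	Retrotransposition	6.85
ZmENODL3/ZmENODL6	Zea mays	0.58564	0.95152	0.61548	Segmental duplication	86.50
ZmENODL12/ZmENODL21	Zea mays	0.07988	0.15477	0.51612	Segmental duplication	14.07
ZmENODL16/ZmENODL24	Zea mays	0.11364	0.31901	0.35623	Segmental duplication	29.00
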