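gene	cortex	frontal_cortex_ba9	cingulate_gyrus	cerebellum	hippocampus	caudate	putamen	spinal_cord
ADAMTS16	22.5	10.47	24.97	9.26	4.37	7.17	1.89	11.32
ALPK3	17.33	3.39	18.69	10.34	4.63	2.91	4.27	4.51
ALS2CR12	15.75	2.05	18.52	13.05	3.48	16.34	22.59	1.2
ANKRD13B	9.2	32.55	1.31	38.25	14.48	16.41	19.79	29.41
BCL9L	3.35	5.57	83.29	5.97	7.99	4	1.83	2.41
BRD3	32.94	14.36	39.97	7.4	8.01	2.97	11.58	7.16
C2orf71	3.01	1.2	3.14	2.88	19.38	1.38	2.41	17.63
C9orf50	11.64	9.52	41.08	21.58	7.16	17.04	13.46	11.21
CACTIN	4.31	16.5	23.48	12.25	9.52	11.37	27.31	3.09
CEP55	1.35	35.8	1.2	15.78	16.36	15.15	14.66	11.15
COL21A1	16.21	53.5	24.49	3.43	7.9	58.03	3.28	7.92
CYP51A1	3.64	14.57	33.63	25.98	4.13	6.19	14.31	6.9
DSC2	72.82	6.28	1.54	6.64	8.54	13.36	8.7	4.54
FBXO42	14.46	6.51	24.56	12.41	10.39	1.2	15.4	3.48
FOLH1	8.12	1.93	5.84	12.21	7.79	31.99	6.37	16.97
INTS1	20	1.61	3.42	3.19	6.28	1.2	14.84	5.76
KAZN	22.42	5.45	8.49	4.11	5.62	9.44	6.19	2.37
KLHL29	3.69	12.25	21.9	2.17	6.76	29.63	5.01	8.19
KNSTRN	25.13	39.13	14.08	18.73	4.67	2.1	12.28	21.27
NUP133	30.58	24.75	2.58	1.2	1.27	17.09	4.06	3.18
OBSCN	17.53	35.26	9.66	39.09	29.14	14.66	66.15	2.66
PEX3	29.61	7.29	3.97	7.87	9.27	6.15	31.9	5.76
PNKD	30.71	1.2	3.49	30.06	63.14	2.84	32.63	4.15
PURG	12.47	2.84	4.25	6.8	15.84	18.55	2.65	7.55
RALGAPA2	4.31	22.44	6.54	17.65	13.96	3.62	4.01	23.89
SLC22A17	39.31	9.23	10.85	4.21	9.59	10.52	5.27	12.14
SPATA6	33.74	32.55	7.11	1.2	12.01	6.02	5.93	16.58
SRSF6	4.77	9.98	6.94	8.17	14.84	57.65	4.26	12.71
TIFAB	7.95	3.19	1.49	7.84	9.58	3.23	8.14	5.18
TNFRSF10A	2.7	5	22.8	11.36	11.56	19.25	8.46	2.67
VPS13B	17.48	15.06	12.73	4	18.15	11.32	85.2	5.98
ZFP57	3.39	2.58	15.87	1.33	10.18	8.27	17.2	9.46
ZNF469	33.09	27.42	3.27	6.89	26.25	14.55	15.84	6.16
ZNF669	2.77	63.61	1.78	103.66	5.29	5.07	11.35	5.05
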