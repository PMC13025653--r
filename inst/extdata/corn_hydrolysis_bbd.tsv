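enzyme_dosage	hydrolysis_time	solid_liquid_ratio	DH	DPPH	ADH	XOD
1.25	2.25	27.5	47.28	53.25	11.75	46.25
1.25	2.25	27.5	46.34	66.81	12.51	44.7
1.5	3	27.5	54.88	12.97	7.74	10.07
1.25	2.25	27.5	48.1	64.49	11.27	44.44
1.25	2.25	27.5	44.17	59.78	16.13	50.39
1.25	3	35	48.99	25.18	9.26	13.67
1.25	1.5	20	24.55	29.36	10.14	13.88
1.25	2.25	27.5	45.18	62.33	14.78	58.72
1.5	1.5	27.5	34.93	13.76	2.18	14.58
1	2.25	35	54.21	27.74	10.95	17.52
1	2.25	20	40.61	15.95	1.92	3.05
1.25	3	20	40.19	22.62	3.05	20.26
1.5	2.25	35	56.54	14.74	6.92	22.62
1	3	27.5	46.72	17.44	1.89	16.61
1.5	2.25	20	44.72	14.69	9.51	18.49
1	1.5	27.5	32.55	24.79	7.31	17.58
1.25	1.5	35	40.37	22.47	4.28	16.83
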