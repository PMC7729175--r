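subject	acc_without	acc_with	acc_total	time_without	time_with	time_total	itr_without	itr_with	itr_total
HS1	75.00	83.33	80.00	10.22	11.26	10.87	7.01	8.25	7.72
HS2	100.00	88.89	94.44	10.67	12.47	11.52	14.53	8.78	11.18
HS3	100.00	100.00	100.00	5.43	7.62	6.74	28.56	20.37	23.01
HS4	100.00	100.00	100.00	6.35	6.72	6.54	24.43	23.08	23.73
HS5	100.00	100.00	100.00	8.68	13.56	11.12	17.86	11.44	13.95
HS6	100.00	100.00	100.00	2.94	3.03	2.98	52.83	51.20	52.00
HS7	100.00	100.00	100.00	4.18	4.61	4.40	37.08	33.63	35.27
HS8	100.00	100.00	100.00	4.33	6.49	5.41	35.82	23.91	28.67
HS9	100.00	91.67	96.67	10.56	12.21	11.18	14.69	9.72	12.32
HS10	100.00	100.00	100.00	3.10	4.93	4.02	50.01	31.43	38.60
HS11	88.89	100.00	94.44	10.13	11.05	10.62	10.80	14.04	12.13
HS12	94.44	88.89	91.67	7.61	8.50	8.04	16.92	12.87	14.75
HS13	83.33	83.33	83.33	13.41	12.34	13.14	6.93	7.52	7.07
HS14	100.00	100.00	100.00	3.57	5.94	4.76	43.45	26.10	32.61
HS15	72.22	77.78	75.00	9.54	11.19	10.40	6.84	7.00	6.89
HS16	66.67	58.33	63.33	11.28	15.50	12.84	4.75	2.47	3.67
HS17	50.00	44.44	47.22	7.51	12.61	9.91	3.39	1.45	2.19
HS18	88.89	66.67	83.33	13.84	10.40	13.15	7.91	5.15	7.06
ALS1	NA	83.33	83.33	NA	9.80	9.80	NA	9.48	9.48
ALS2	NA	75.00	75.00	NA	8.72	8.72	NA	8.21	8.21
ALS3	NA	100.00	100.00	NA	7.40	7.40	NA	20.96	20.96
ALS4	NA	100.00	100.00	NA	10.12	10.12	NA	15.33	15.33
ALS5	77.78	66.67	73.33	9.56	14.83	11.47	8.19	3.61	5.91
ALS6	100.00	100.00	100.00	4.39	5.72	5.06	35.31	27.10	30.66
ALS7	100.00	88.89	94.44	4.84	7.19	5.94	32.05	15.23	21.67
ALS8	100.00	100.00	100.00	6.16	5.56	5.86	25.17	27.90	26.46
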