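population	n	category	carriers	carriers_pct	nroh	nroh_pct	nroh_per_ind	sroh_mb	sroh_pct	sroh_per_ind	mean_length_mb
SPEA	35	ROH1	35	100	14271	65.59	407.74	5411.68	46.56	154.62	0.38
SPEA	35	ROH2	35	100	6216	28.57	177.60	4091.61	35.21	116.90	0.66
SPEA	35	ROH3	35	100	1053	4.84	30.09	1360.82	11.71	38.88	1.29
SPEA	35	ROH4	35	100	170	0.78	4.86	435.08	3.74	12.43	2.56
SPEA	35	ROH5	28	80.00	39	0.18	1.11	211.20	1.82	6.03	5.41
SPEA	35	ROH6	7	20.00	8	0.04	0.23	111.71	0.96	3.19	13.96
SPEA	35	TOTAL	NA	NA	21757	100	621.63	11622.10	100	332.06	0.53
SPWA	35	ROH1	35	100	14293	65.25	408.37	5412.04	44.91	154.63	0.38
SPWA	35	ROH2	35	100	6292	28.72	179.77	4145.74	34.41	118.45	0.66
SPWA	35	ROH3	35	100	1069	4.88	30.54	1374.31	11.41	39.27	1.29
SPWA	35	ROH4	35	100	171	0.78	4.89	452.66	3.76	12.93	2.65
SPWA	35	ROH5	30	85.71	56	0.26	1.60	315.76	2.62	9.02	5.64
SPWA	35	ROH6	14	40.00	24	0.11	0.69	347.86	2.89	9.94	14.49
SPWA	35	TOTAL	NA	NA	21905	100	625.86	12048.36	100	344.24	0.55
SPOR	35	ROH1	35	100	14031	66.15	400.89	5302.19	47.05	151.49	0.38
SPOR	35	ROH2	35	100	5979	28.18	170.83	3960.24	35.14	113.15	0.66
SPOR	35	ROH3	35	100	1004	4.73	28.69	1262.25	11.20	36.06	1.26
SPOR	35	ROH4	35	100	158	0.74	4.51	406.06	3.60	11.60	2.57
SPOR	35	ROH5	27	77.14	30	0.14	0.86	163.87	1.45	4.68	5.46
SPOR	35	ROH6	9	25.71	12	0.06	0.34	175.66	1.56	5.02	14.64
SPOR	35	TOTAL	NA	NA	21214	100	606.11	11270.26	100	322.01	0.53
MAAS	15	ROH1	15	100	4768	63.76	317.87	1806.92	37.57	120.46	0.38
MAAS	15	ROH2	15	100	2141	28.63	142.73	1418.38	29.49	94.56	0.66
MAAS	15	ROH3	15	100	408	5.46	27.20	524.88	10.91	34.99	1.29
MAAS	15	ROH4	15	100	94	1.26	6.27	250.42	5.21	16.69	2.66
MAAS	15	ROH5	13	86.67	30	0.40	2.00	162.60	3.38	10.84	5.42
MAAS	15	ROH6	9	60	37	0.49	2.47	645.69	13.43	43.05	17.45
MAAS	15	TOTAL	NA	NA	7478	100	498.53	4808.89	100	320.59	0.64
MABO	10	ROH1	10	100	3132	65.33	313.20	1186.21	36.06	118.62	0.38
MABO	10	ROH2	10	100	1298	27.08	129.80	862.85	26.23	86.28	0.66
MABO	10	ROH3	10	100	246	5.13	24.60	315.16	9.58	31.52	1.28
MABO	10	ROH4	10	100	63	1.31	6.30	171.63	5.22	17.16	2.72
MABO	10	ROH5	9	90	24	0.50	2.40	133.14	4.05	13.31	5.55
MABO	10	ROH6	5	50	31	0.65	3.10	620.22	18.86	62.02	20.00
MABO	10	TOTAL	NA	NA	4794	100	479.40	3289.22	100	328.92	0.69
MAFI	9	ROH1	9	100	2776	62.46	308.44	1051.46	34.19	116.83	0.38
MAFI	9	ROH2	9	100	1271	28.60	141.22	841.51	27.36	93.50	0.66
MAFI	9	ROH3	9	100	250	5.63	27.78	322.73	10.49	35.86	1.29
MAFI	9	ROH4	9	100	82	1.85	9.11	228.63	7.43	25.40	2.79
MAFI	9	ROH5	9	100	37	0.83	4.11	204.92	6.66	22.77	5.54
MAFI	9	ROH6	6	66.66	28	0.63	3.11	426.60	13.87	47.40	15.24
MAFI	9	TOTAL	NA	NA	4444	100	493.78	3075.84	100	341.76	0.69
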